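test_that("bead generator renders the stated optics", {
  # point emitter: image FWHM equals the PSF FWHM
  pt <- generate_bead_stack(diameter = 0, psf_fwhm = 320, pixel_size = 20,
                            n_beads = 3, seed = 1)
  prof <- extract_bead_profile(pt$volume, round(unlist(pt$truth$beads[1, 1:2])),
                               c(0, 1), half_length = 800)
  expect_equal(fit_gaussian(prof)$fwhm, 320, tolerance = 1 / 320)

  # 100 nm bead with PSF chosen so the rendered profile measures 320 nm
  bs <- fx_bead_stack()
  prof2 <- extract_bead_profile(bs$volume, round(unlist(bs$truth$beads[1, 1:2])),
                                c(0, 1), half_length = 800)
  expect_equal(fit_gaussian(prof2)$fwhm, 320, tolerance = 2 / 320)

  # determinism: identical seeds give bitwise-identical volumes
  again <- generate_bead_stack(diameter = 100, psf_fwhm = PSF_FOR_320,
                               pixel_size = 20, n_beads = 6, seed = 2)
  expect_identical(again$volume$voxels, bs$volume$voxels)
  expect_identical(again$truth$beads, bs$truth$beads)

  # placement respects the 3x PSF separation or refuses
  expect_error(generate_bead_stack(100, 320, 20, n_beads = 50,
                                   field_shape = c(1, 80, 80), seed = 1),
               "field too small")
})

test_that("default and finely sub-sampled bead renderers agree", {
  # area-weighting at 8x vs 10x finer sub-sampling, diameter/psf = 0.31
  coarse <- generate_bead_stack(100, 320, 25, n_beads = 1, seed = 5,
                                supersample = 8L)
  fine <- generate_bead_stack(100, 320, 25, n_beads = 1, seed = 5,
                              supersample = 80L)
  f1 <- fit_gaussian(extract_bead_profile(coarse$volume,
        round(unlist(coarse$truth$beads[1, 1:2])), c(0, 1), 800))$fwhm
  f2 <- fit_gaussian(extract_bead_profile(fine$volume,
        round(unlist(fine$truth$beads[1, 1:2])), c(0, 1), 800))$fwhm
  expect_lt(abs(f1 - f2), 2)
})

test_that("tissue phantom channels reflect their generating structures", {
  # nuclei only: SRS and DAPI-like channel share support
  spec <- quiet_spec(field_shape = c(1, 96, 96), seed = 3,
                     structures = list(structure_spec("nucleus", count = 3)))
  ph <- generate_tissue_phantom(spec)
  expect_setequal(names(ph$channels), c("CH3-2940", "DAPI"))
  srs_sup <- ph$channels[["CH3-2940"]]$voxels > 0.05
  dapi_sup <- ph$channels[["DAPI"]]$voxels > 0.05
  expect_gt(mean(srs_sup == dapi_sup), 0.99)

  # default 4-structure phantom: maps pairwise distinct, all on the composite
  ph4 <- generate_tissue_phantom(phantom_spec(seed = 7))
  kinds <- names(ph4$truth$maps)
  expect_true(length(kinds) >= 4)
  for (i in seq_along(kinds)) for (j in seq_len(i - 1))
    expect_false(identical(ph4$truth$maps[[kinds[i]]],
                           ph4$truth$maps[[kinds[j]]]))
  srs_sup4 <- ph4$channels[["CH3-2940"]]$voxels >
    median(ph4$channels[["CH3-2940"]]$voxels)
  for (k in setdiff(kinds, "chromosome_void"))
    expect_gt(mean(srs_sup4[ph4$truth$maps[[k]] > 0.5]), 0.5)

  # determinism
  expect_identical(generate_tissue_phantom(phantom_spec(seed = 7))$channels[["CH3-2940"]]$voxels,
                   ph4$channels[["CH3-2940"]]$voxels)
})

test_that("SRS forward model is linear and additive in its components", {
  spec <- quiet_spec(field_shape = c(1, 96, 96), seed = 8,
                     structures = list(structure_spec("soma", count = 3,
                                                      protein_density = 0.8)))
  ph <- generate_tissue_phantom(spec)

  # doubling protein density doubles the noiseless composite
  spec2 <- spec; spec2$structures[[1]]$protein_density <- 1.6
  twice <- srs_forward_model(ph$truth, spec2)
  expect_equal(twice$voxels, 2 * ph$channels[["CH3-2940"]]$voxels,
               tolerance = 1e-12)

  # all retentions zero, no background: identically zero
  spec0 <- spec; spec0$structures[[1]]$retention <- 0
  expect_equal(max(abs(srs_forward_model(ph$truth, spec0)$voxels)), 0)

  # uniform water background shifts the out-of-structure mean exactly
  specw <- spec; specw$background <- background_spec(0, 0.3)
  with_bg <- srs_forward_model(ph$truth, specw)
  outside <- ph$truth$maps$soma < 1e-9
  far <- outside & ph$channels[["CH3-2940"]]$voxels < 1e-6
  expect_equal(unique(round(with_bg$voxels[far] - ph$channels[["CH3-2940"]]$voxels[far], 9)),
               0.3)

  # composite equals the voxelwise sum of single-kind renders
  multi <- quiet_spec(field_shape = c(1, 96, 96), seed = 12,
                      structures = list(structure_spec("nucleus", count = 2),
                                        structure_spec("vessel", count = 2)))
  phm <- generate_tissue_phantom(multi)
  parts <- lapply(c("nucleus", "vessel"), function(k) {
    sp <- multi
    sp$structures <- Filter(function(s) s$kind == k, multi$structures)
    tr <- phm$truth; tr$maps <- tr$maps[k]
    srs_forward_model(tr, sp)$voxels
  })
  expect_equal(phm$channels[["CH3-2940"]]$voxels, parts[[1]] + parts[[2]],
               tolerance = 1e-12)
})

test_that("simulated expansion scales geometry and dilutes signal cubically", {
  spec <- quiet_spec(field_shape = c(1, 160, 160), seed = 9,
                     structures = list(structure_spec("nucleus", count = 4)))
  ph <- generate_tissue_phantom(spec)

  # ratio 1 with no distortion is the identity
  ex1 <- simulate_expansion(ph, ratio = 1)
  expect_equal(ex1$post[["CH3-2940"]]$voxels, ex1$pre[["CH3-2940"]]$voxels,
               tolerance = 1e-12)

  ex <- simulate_expansion(ph, ratio = 4)
  mp <- mean(ex$pre[["CH3-2940"]]$voxels[truth_mask(ph$truth, "nucleus", 4)])
  mq <- mean(ex$post[["CH3-2940"]]$voxels[truth_mask(ex$truth, "nucleus", 12)])
  expect_equal(mp / mq, 64, tolerance = 0.02)
  expect_identical(ex$post[["CH3-2940"]]$expansion_factor, 4)
  expect_identical(ex$post[["CH3-2940"]]$expansion_state, "expanded")

  # conservation: in-plane scaling by r multiplies map mass by r^2 (<= 1%)
  expect_equal(sum(ex$truth$maps$nucleus) / sum(ph$truth$maps$nucleus), 16,
               tolerance = 0.01)

  # a feature of true pre-size L measures ratio * L in post physical units
  ex42 <- simulate_expansion(ph, ratio = 4.2)
  width <- function(map) {
    cols <- which(apply(map[1, , ] > 0.5, 1, any))
    diff(range(cols)) + 1
  }
  expect_equal(width(ex42$truth$maps$nucleus) / width(ph$truth$maps$nucleus),
               4.2, tolerance = 0.05)

  # a smooth random distortion field hits the requested RMS and roughly
  # conserves structure mass
  exd <- simulate_expansion(ph, ratio = 3, distortion_rms = 1500, seed = 2)
  ex3 <- simulate_expansion(ph, ratio = 3, distortion_rms = 0, seed = 2)
  f <- exd$truth$expansion$field
  expect_equal(sqrt(mean(f$dy^2 + f$dx^2)), 1500 / 497, tolerance = 1e-8)
  expect_equal(sum(exd$truth$maps$nucleus), sum(ex3$truth$maps$nucleus),
               tolerance = 0.02)
  expect_false(identical(exd$post[["CH3-2940"]]$voxels,
                         ex3$post[["CH3-2940"]]$voxels))
})

test_that("ground-truth degradation adds calibrated Gaussian noise", {
  v <- image_volume(matrix(5, 120, 120), 100)
  expect_identical(degrade_ground_truth(v, 0), v)
  d <- degrade_ground_truth(v, 0.7, seed = 4)
  expect_equal(sd(d$voxels), 0.7, tolerance = 0.05)
  expect_equal(mean(d$voxels), 5, tolerance = 0.05)
  expect_identical(degrade_ground_truth(v, 0.7, seed = 4)$voxels, d$voxels)
  expect_false(identical(degrade_ground_truth(v, 0.7, seed = 5)$voxels,
                         d$voxels))
})
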