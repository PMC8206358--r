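test_that("Gaussian profile fitting recovers width, center and offset", {
  t <- seq(-500, 500, by = 10)
  y <- exp(-(t - 3)^2 / (2 * 100^2))
  fit <- fit_gaussian(line_profile(t, y))
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)) * 100, tolerance = 0.1 / 235)
  expect_equal(fit$center, 3, tolerance = 1e-6)

  # offset invariance
  fit2 <- fit_gaussian(line_profile(t, y + 10))
  expect_equal(fit2$fwhm, fit$fwhm, tolerance = 1e-8)
  expect_equal(fit2$offset, 10, tolerance = 1e-6)
  expect_gt(fit2$goodness, 0.999999)

  # rendered 100 nm bead with PSF FWHM 314.4: measured ~320
  bs <- fx_bead_stack()
  prof <- extract_bead_profile(bs$volume, round(unlist(bs$truth$beads[1, 1:2])),
                               c(0, 1), half_length = 800)
  expect_equal(fit_gaussian(prof)$fwhm, 320, tolerance = 2 / 320)

  expect_error(fit_gaussian(line_profile(t, rep(1, length(t)))), "peak")
})

test_that("bead profiles are centered, symmetric, and isotropic", {
  bs <- fx_bead_stack()
  truth <- bs$truth$beads[1, ]
  prof <- extract_bead_profile(bs$volume, round(c(truth$y_px, truth$x_px)),
                               c(0, 1), half_length = 600)
  fit <- fit_gaussian(prof)
  # recovered peak within half a pixel (10 nm) of the true center offset
  true_off <- (truth$x_px - round(truth$x_px)) * 20
  expect_lt(abs(fit$center - true_off), 10)

  # noiseless bead: profile symmetric about its center to interpolation tol
  i <- seq_along(prof$positions)
  ctr <- which.min(abs(prof$positions - fit$center))
  k <- min(ctr - 1, length(i) - ctr)
  expect_equal(prof$intensities[ctr + 1:k], prof$intensities[ctr - 1:k],
               tolerance = 0.02)

  # orthogonal directions agree within 2%
  fy <- fit_gaussian(extract_bead_profile(bs$volume,
        round(c(truth$y_px, truth$x_px)), c(1, 0), 600))
  expect_equal(fy$fwhm, fit$fwhm, tolerance = 0.02)

  expect_error(extract_bead_profile(bs$volume, round(c(truth$y_px, truth$x_px)),
                                    c(0, 1), half_length = 1e6), "exits")
  flat <- image_volume(matrix(0, 32, 32), 20)
  expect_error(extract_bead_profile(flat, c(16, 16), c(0, 1), 100),
               "local maximum|peak")
})

test_that("bead object-function deconvolution inverts the forward model", {
  # zero-size object: PSF equals the measurement
  expect_equal(deconvolve_bead(320, 0)$psf_fwhm, 320)

  # round trip at several PSF widths, 1 nm agreement
  for (g in c(250, 314, 400)) {
    meas <- vistar:::disk_gaussian_fwhm(g, 100)
    expect_lt(abs(deconvolve_bead(meas, 100)$psf_fwhm - g), 1)
  }

  # monotone: wider measurement, wider PSF
  psfs <- vapply(c(300, 320, 340, 380),
                 function(m) deconvolve_bead(m, 100)$psf_fwhm, 0)
  expect_true(all(diff(psfs) > 0))

  # vanishing-diameter limit
  expect_lt(abs(deconvolve_bead(320, 1)$psf_fwhm - 320), 0.1)

  expect_error(deconvolve_bead(40, 100), "not deconvolvable")
  expect_error(deconvolve_bead(60, 100), "no PSF root")
})

test_that("expansion-corrected effective resolution is a plain division", {
  expect_equal(effective_resolution(382, 1), 382)
  expect_equal(effective_resolution(382, 2), 191)
  expect_equal(round(effective_resolution(382, 4.2)), 91)
  expect_error(effective_resolution(382, 0.8), ">= 1")
})

test_that("stack calibration recovers the generating PSF", {
  stack20 <- generate_bead_stack(100, PSF_FOR_320, 20, n_beads = 20, seed = 3)
  rep <- calibrate_from_stack(stack20$volume, bead_diameter = 100,
                              expansion_factor = 4.2)
  expect_equal(rep$psf_fwhm, PSF_FOR_320, tolerance = 0.02)
  expect_lte(rep$psf_fwhm, rep$measured_fwhm)
  expect_equal(rep$effective_resolution, rep$rayleigh_resolution / 4.2)
  expect_true(nrow(rep$per_bead) >= 20)

  # shot + read noise at peak SNR ~ 20: still within 5%
  noisy <- generate_bead_stack(100, PSF_FOR_320, 20, n_beads = 20, seed = 6,
                               amplitude = 15,
                               noise = noise_spec("poisson_gaussian",
                                                  read_sigma = 0.05,
                                                  photon_scale = 50))
  repn <- calibrate_from_stack(noisy$volume, bead_diameter = 100)
  expect_equal(repn$psf_fwhm, PSF_FOR_320, tolerance = 0.05)

  # single centered bead reduces to the single-profile pipeline
  one <- generate_bead_stack(100, PSF_FOR_320, 20, n_beads = 1, seed = 8)
  rep1 <- calibrate_from_stack(one$volume, bead_diameter = 100)
  ctr <- round(unlist(one$truth$beads[1, 1:2]))
  manual <- mean(c(
    fit_gaussian(extract_bead_profile(one$volume, ctr, c(0, 1),
                                      2.5 * rep1$measured_fwhm))$fwhm,
    fit_gaussian(extract_bead_profile(one$volume, ctr, c(1, 0),
                                      2.5 * rep1$measured_fwhm))$fwhm))
  expect_equal(rep1$measured_fwhm, manual, tolerance = 1e-3)

  expect_error(calibrate_from_stack(image_volume(matrix(rnorm(900, 0, 1e-4), 30, 30), 20), 100),
               "no beads")
})
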