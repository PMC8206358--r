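# Shared, lazily built fixtures.  Everything is generated in code from
# seeded phantom specs; heavy objects (trained models, phantom batteries)
# are cached for the duration of the test run.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

# PSF FWHM whose convolution with a 100 nm circle measures 320 nm
PSF_FOR_320 <- 314.4312

# quiet spec: no background, no noise — for analytic checks
quiet_spec <- function(...) {
  args <- list(...)
  defaults <- list(background = background_spec(0, 0),
                   noise = noise_spec("gaussian", read_sigma = 0))
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# standard noiseless bead field: 100 nm beads, fine 20 nm pixels
fx_bead_stack <- function() fx("bead_stack",
  generate_bead_stack(diameter = 100, psf_fwhm = PSF_FOR_320, pixel_size = 20,
                      n_beads = 6, seed = 2))

# eight single-slice tissue phantoms used by the training benchmarks
fx_training_volumes <- function() fx("training_volumes",
  lapply(1:8, function(i) {
    ph <- generate_tissue_phantom(phantom_spec(field_shape = c(1, 96, 96),
                                               seed = 200 + i))
    ph$channels[["CH3-2940"]]
  }))

identity_config <- function() train_config(patch_size = 32L, batch_size = 8L,
                                           steps = 800L, depth = 1L,
                                           base_channels = 8L,
                                           rolling_ball_radius = 15L, seed = 0L)

fx_identity_dataset <- function() fx("identity_dataset", {
  vols <- fx_training_volumes()
  build_dataset(vols, vols, identity_config())
})

fx_identity_model <- function() fx("identity_model",
  train_unet(fx_identity_dataset(), identity_config()))

# vessel virtual-staining benchmark: SRS composite -> lectin channel
vessel_config <- function() train_config(patch_size = 48L, batch_size = 8L,
                                         steps = 400L, depth = 2L,
                                         base_channels = 8L,
                                         rolling_ball_radius = 15L, seed = 0L)

fx_vessel_dataset <- function() fx("vessel_dataset", {
  phs <- lapply(1:8, function(i)
    generate_tissue_phantom(phantom_spec(field_shape = c(1, 128, 128),
                                         seed = 300 + i)))
  build_dataset(lapply(phs, function(p) p$channels[["CH3-2940"]]),
                lapply(phs, function(p) p$channels[["lectin"]]),
                vessel_config())
})

fx_vessel_model <- function() fx("vessel_model",
  train_unet(fx_vessel_dataset(), vessel_config()))

# expansion-ratio recovery battery: 20 seeded phantoms, ratios in [3, 4.5]
fx_ratio_battery <- function() fx("ratio_battery", {
  set.seed(42)
  res <- data.frame(true = numeric(0), est = numeric(0))
  for (k in 1:20) {
    r <- runif(1, 3, 4.5)
    ph <- generate_tissue_phantom(phantom_spec(seed = 100 + k))
    ex <- simulate_expansion(ph, ratio = r, seed = k)
    est <- tryCatch(estimate_expansion_ratio(ex$pre[["CH3-2940"]],
                                             ex$post[["CH3-2940"]])$ratio,
                    error = function(e) NA_real_)
    res <- rbind(res, data.frame(true = r, est = est))
  }
  res
})

# identity-task noise-robustness curve (shared by evaluation + acceptance)
curve_config <- function() train_config(patch_size = 32L, batch_size = 8L,
                                        steps = 250L, depth = 1L,
                                        base_channels = 6L,
                                        rolling_ball_radius = 15L, seed = 0L)

fx_noise_curve <- function() fx("noise_curve", {
  vols <- fx_training_volumes()
  ds <- build_dataset(vols, vols, curve_config())
  noise_robustness_curve(ds, curve_config(), sigmas = c(0, 0.5, 2), seed = 3)
})

# brute-force rolling-ball reference (direct O(N r^2) sliding ball)
rolling_ball_reference <- function(img, r) {
  H <- nrow(img); W <- ncol(img)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  offs$h <- sqrt(r^2 - offs$dy^2 - offs$dx^2)
  sweep_one <- function(src, sign) {
    out <- matrix(0, H, W)
    for (y in 1:H) for (x in 1:W) {
      v <- sign * Inf
      for (k in seq_len(nrow(offs))) {
        yy <- y + offs$dy[k]; xx <- x + offs$dx[k]
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= W) {
          cand <- src[yy, xx] - sign * offs$h[k]
          v <- if (sign > 0) min(v, cand) else max(v, cand)
        }
      }
      out[y, x] <- v
    }
    out
  }
  bg <- sweep_one(sweep_one(img, 1), -1)
  pmax(img - bg, 0)
}
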