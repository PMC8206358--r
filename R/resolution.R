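# Optical-resolution calibration from bead images: cross-section profile
# extraction, Gaussian fitting, deconvolution of the circular bead object
# function under a Gaussian-PSF forward model, Rayleigh conversion, and
# expansion-corrected effective resolution.

FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))   # 2.35482...

#' Line profile across an image feature
#'
#' @param positions strictly increasing sample positions, nm.
#' @param intensities intensities at those positions, arbitrary units.
#' @export
line_profile <- function(positions, intensities) {
  stopifnot(length(positions) == length(intensities), length(positions) >= 7)
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities)),
            class = "line_profile")
}

#' Extract a bead cross-section profile from an image volume
#'
#' The stated center is refined to the local intensity centroid (the bead
#' must sit within 1 px of a local maximum), then intensities are sampled
#' by bilinear interpolation at pixel-size spacing along the line through
#' the refined centroid.  Sampling uses the maximum-intensity projection of
#' the stack.
#'
#' @param v an [image_volume()].
#' @param center approximate `(y, x)` bead center, 1-based pixels.
#' @param direction length-2 direction vector (normalized internally).
#' @param half_length half line length, nm.
#' @return a [line_profile()].
#' @export
extract_bead_profile <- function(v, center, direction = c(0, 1),
                                 half_length) {
  img <- max_intensity_projection(v)
  px <- v$pixel_size_xy
  H <- nrow(img); W <- ncol(img)
  cy <- round(center[1]); cx <- round(center[2])
  if (cy < 2 || cy > H - 1 || cx < 2 || cx > W - 1)
    stop("center too close to the image border")
  win <- img[(cy - 1):(cy + 1), (cx - 1):(cx + 1)]
  k <- which(win == max(win), arr.ind = TRUE)[1, ]
  cy <- cy + k[1] - 2L; cx <- cx + k[2] - 2L
  nb <- img[max(1, cy - 1):min(H, cy + 1), max(1, cx - 1):min(W, cx + 1)]
  if (img[cy, cx] < max(nb) || max(nb) <= min(nb))
    stop("no local maximum within 1 px of the stated center")
  # centroid refinement over a small window, background-floored
  r <- 2L
  ys <- max(1, cy - r):min(H, cy + r); xs <- max(1, cx - r):min(W, cx + r)
  wts <- pmax(img[ys, xs] - min(img[ys, xs]), 0)
  if (sum(wts) > 0) {
    cyf <- sum(outer(ys, rep(1, length(xs))) * wts) / sum(wts)
    cxf <- sum(outer(rep(1, length(ys)), xs) * wts) / sum(wts)
  } else { cyf <- cy; cxf <- cx }
  d <- direction / sqrt(sum(direction^2))
  t_nm <- seq(-half_length, half_length, by = px)
  yy <- cyf + t_nm / px * d[1]
  xx <- cxf + t_nm / px * d[2]
  if (any(yy < 1 | yy > H | xx < 1 | xx > W))
    stop("profile line exits the image; shorten half_length")
  line_profile(t_nm, bilinear_sample(img, yy, xx))
}

#' Fit a Gaussian to a line profile
#'
#' Least-squares fit of `A * exp(-(t - mu)^2 / (2 sigma^2)) + B`; the
#' reported FWHM is `2 sqrt(2 ln 2) sigma`.
#'
#' @param p a [line_profile()] with a single dominant peak.
#' @return class `gaussian_fit`: amplitude, center (nm), sigma (nm),
#'   offset, fwhm (nm), goodness (R^2).
#' @export
fit_gaussian <- function(p) {
  stopifnot(inherits(p, "line_profile"))
  t <- p$positions; y <- p$intensities
  off0 <- min(y); amp0 <- max(y) - off0
  if (amp0 <= 0) stop("profile has no peak to fit")
  mu0 <- t[which.max(y)]
  above <- which(y - off0 > amp0 / 2)
  sig0 <- max(diff(range(t[above])), diff(t)[1]) / FWHM_PER_SIGMA
  # analytic gradient: numeric differentiation degenerates when a start
  # value is exactly zero (e.g. a centered peak)
  gauss_grad <- deriv(~ A * exp(-(t - mu)^2 / (2 * s^2)) + B,
                      c("A", "mu", "s", "B"),
                      function(t, A, mu, s, B) NULL)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ gauss_grad(t, A, mu, s, B),
                      start = list(A = amp0, mu = mu0, s = sig0, B = off0),
                      lower = c(0, min(t), 1e-9, -Inf),
                      upper = c(Inf, max(t), diff(range(t)), Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Gaussian fit failed to converge: ", conditionMessage(e),
           " (peak residual range ", signif(diff(range(y)), 4), ")"))
  cf <- coef(fit)
  res <- y - predict(fit)
  r2 <- 1 - sum(res^2) / max(sum((y - mean(y))^2), 1e-300)
  structure(list(amplitude = unname(cf["A"]), center = unname(cf["mu"]),
                 sigma = unname(cf["s"]), offset = unname(cf["B"]),
                 fwhm = unname(FWHM_PER_SIGMA * cf["s"]), goodness = r2),
            class = "gaussian_fit")
}

# Central line-profile FWHM of a uniform disc of the given diameter
# convolved with an isotropic 2-D Gaussian PSF.  The 2-D convolution
# reduces to a 1-D integral over chords:
#   I(x) = int_{-R}^{R} phi((x-u)/sigma)/sigma * (2 Phi(sqrt(R^2-u^2)/sigma) - 1) du
# evaluated by Simpson quadrature on a grid far finer than the FWHM.
disk_gaussian_profile <- function(x, sigma, R, n = NULL) {
  if (is.null(n)) {  # resolve both the disc and a possibly narrow Gaussian
    n <- max(801, min(100001, ceiling(8 * R / sigma)))
    if (n %% 2 == 0) n <- n + 1
  }
  u <- seq(-R, R, length.out = n)
  h <- u[2] - u[1]
  w <- rep(c(2, 4), length.out = n); w[1] <- 1; w[n] <- 1
  chord <- 2 * pnorm(sqrt(pmax(R^2 - u^2, 0)) / sigma) - 1
  vapply(x, function(xi)
    sum(w * dnorm((xi - u) / sigma) / sigma * chord) * h / 3, 0)
}

disk_gaussian_fwhm <- function(psf_fwhm, diameter) {
  sigma <- psf_fwhm / FWHM_PER_SIGMA
  R <- diameter / 2
  if (R <= 0) return(psf_fwhm)
  I0 <- disk_gaussian_profile(0, sigma, R)
  f <- function(x) disk_gaussian_profile(x, sigma, R) - I0 / 2
  2 * uniroot(f, c(0, R + 6 * sigma), tol = 1e-6)$root
}

#' Deconvolve the bead object function from a measured FWHM
#'
#' Finds, by monotone root search on the forward model, the Gaussian PSF
#' whose convolution with a uniform circle of the given diameter has a
#' central line-profile FWHM equal to the measurement, then converts to a
#' Rayleigh-criterion resolution (`1.22 *` PSF FWHM).
#'
#' @param measured_fwhm fitted bead-image FWHM, nm.
#' @param bead_diameter physical bead diameter, nm.
#' @param rayleigh_factor Rayleigh conversion factor applied to the PSF FWHM.
#' @return `list(psf_fwhm, rayleigh_resolution)` in nm.
#' @export
deconvolve_bead <- function(measured_fwhm, bead_diameter,
                            rayleigh_factor = 1.22) {
  stopifnot(measured_fwhm > 0, bead_diameter >= 0)
  if (measured_fwhm <= bead_diameter / 2)
    stop("measured FWHM below half the bead diameter: not deconvolvable")
  if (bead_diameter == 0)
    return(list(psf_fwhm = measured_fwhm,
                rayleigh_resolution = rayleigh_factor * measured_fwhm))
  f <- function(g) disk_gaussian_fwhm(g, bead_diameter) - measured_fwhm
  lo <- 1e-3 * measured_fwhm
  if (f(lo) >= 0)
    stop("no PSF root in bracket: measured FWHM (", measured_fwhm,
         " nm) does not exceed the bare object width")
  g <- uniroot(f, c(lo, measured_fwhm), tol = 1e-4)$root
  list(psf_fwhm = g, rayleigh_resolution = rayleigh_factor * g)
}

#' Expansion-corrected effective resolution
#'
#' Physical expansion magnifies the sample before the optics, so the
#' resolution in pre-expansion sample coordinates is the optical Rayleigh
#' resolution divided by the linear expansion factor.  Reports round this
#' to the nearest nanometer.
#'
#' @param rayleigh_resolution optical resolution, nm.
#' @param expansion_factor linear expansion ratio (>= 1).
#' @return effective resolution in nm (unrounded).
#' @export
effective_resolution <- function(rayleigh_resolution, expansion_factor) {
  stopifnot(rayleigh_resolution > 0)
  if (expansion_factor < 1)
    stop("expansion_factor must be >= 1")
  rayleigh_resolution / expansion_factor
}

# Local maxima of `img` at or above `thr` (8-neighborhood, >= comparison).
find_local_maxima <- function(img, thr) {
  H <- nrow(img); W <- ncol(img)
  core <- img[2:(H - 1), 2:(W - 1)]
  ok <- core >= thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ok <- ok & core >= img[2:(H - 1) + dy, 2:(W - 1) + dx]
  }
  idx <- which(ok, arr.ind = TRUE)
  cbind(y = idx[, 1] + 1L, x = idx[, 2] + 1L)
}

#' Calibrate optical resolution from a bead stack
#'
#' Detects beads (local maxima of the lightly smoothed projection above a
#' robust `median + 5 * MAD` threshold, duplicates within one estimated
#' FWHM merged), extracts two orthogonal cross-section profiles per bead,
#' fits Gaussians, averages the fitted FWHM over beads and directions, then
#' deconvolves the bead object function and applies the Rayleigh criterion
#' and the expansion correction.
#'
#' @param v an [image_volume()] containing beads.
#' @param bead_diameter physical bead diameter, nm.
#' @param expansion_factor linear expansion ratio (default 1, unexpanded).
#' @param half_length profile half-length in nm (default: 2.5x the first
#'   fitted FWHM).
#' @param rayleigh_factor see [deconvolve_bead()].
#' @return class `resolution_report`: `measured_fwhm`, `bead_diameter`,
#'   `psf_fwhm`, `rayleigh_resolution`, `expansion_factor`,
#'   `effective_resolution` (all nm) and a `per_bead` data frame of fits.
#' @export
calibrate_from_stack <- function(v, bead_diameter, expansion_factor = 1,
                                 half_length = NULL, rayleigh_factor = 1.22) {
  stopifnot(inherits(v, "vista_volume"))
  img <- max_intensity_projection(v)
  px <- v$pixel_size_xy
  sm <- blur2d(img, 1)
  thr <- median(sm) + 5 * mad(sm)
  peaks <- find_local_maxima(sm, thr)
  if (nrow(peaks) == 0) stop("no beads detected above the robust threshold")
  ord <- order(sm[peaks], decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]

  # provisional FWHM from the brightest bead fixes the merge radius
  first_hl <- if (is.null(half_length)) 6 * px * 3 else half_length
  first <- fit_gaussian(extract_bead_profile(v, peaks[1, ], c(0, 1),
                                             half_length = first_hl))
  merge_px <- max(first$fwhm / px, 2)
  kept <- matrix(peaks[1, ], 1, 2)
  for (i in seq_len(nrow(peaks))[-1]) {
    d2 <- (kept[, 1] - peaks[i, 1])^2 + (kept[, 2] - peaks[i, 2])^2
    if (min(d2) >= merge_px^2) kept <- rbind(kept, peaks[i, ])
  }
  hl <- if (is.null(half_length)) 2.5 * first$fwhm else half_length

  rows <- list()
  for (i in seq_len(nrow(kept))) {
    for (dir in list(c(0, 1), c(1, 0))) {
      fit <- tryCatch(
        fit_gaussian(extract_bead_profile(v, kept[i, ], dir, half_length = hl)),
        error = function(e) NULL)
      if (!is.null(fit))
        rows[[length(rows) + 1L]] <-
          data.frame(bead = i, y_px = kept[i, 1], x_px = kept[i, 2],
                     dir_y = dir[1], dir_x = dir[2],
                     fwhm_nm = fit$fwhm, r_squared = fit$goodness)
    }
  }
  if (length(rows) == 0) stop("no bead profile could be fitted")
  per_bead <- do.call(rbind, rows)
  measured <- mean(per_bead$fwhm_nm)
  dec <- deconvolve_bead(measured, bead_diameter,
                         rayleigh_factor = rayleigh_factor)
  structure(list(measured_fwhm = measured, bead_diameter = bead_diameter,
                 psf_fwhm = dec$psf_fwhm,
                 rayleigh_resolution = dec$rayleigh_resolution,
                 expansion_factor = expansion_factor,
                 effective_resolution =
                   effective_resolution(dec$rayleigh_resolution,
                                        expansion_factor),
                 per_bead = per_bead),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat("<resolution_report>\n")
  cat(sprintf("  beads fitted          : %d profiles on %d beads\n",
              nrow(x$per_bead), length(unique(x$per_bead$bead))))
  cat(sprintf("  measured FWHM         : %.1f nm (bead diameter %g nm)\n",
              x$measured_fwhm, x$bead_diameter))
  cat(sprintf("  deconvolved PSF FWHM  : %.1f nm\n", x$psf_fwhm))
  cat(sprintf("  Rayleigh resolution   : %.1f nm\n", x$rayleigh_resolution))
  cat(sprintf("  effective resolution  : %.0f nm at %gx expansion\n",
              x$effective_resolution, x$expansion_factor))
  invisible(x)
}
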