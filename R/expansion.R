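# Expansion-ratio estimation by log-polar spectral registration of
# pre/post maximum-intensity projections, and protein-retention
# quantification with volumetric signal-dilution correction.

fftshift2 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  m[c(((H %/% 2) + 1):H, 1:(H %/% 2)), c(((W %/% 2) + 1):W, 1:(W %/% 2))]
}

hann2 <- function(H, W) {
  wy <- 0.5 * (1 - cos(2 * pi * (seq_len(H) - 1) / (H - 1)))
  wx <- 0.5 * (1 - cos(2 * pi * (seq_len(W) - 1) / (W - 1)))
  outer(wy, wx)
}

# Normalized cross-power phase correlation.  Returns the (possibly
# sub-pixel) shift of `b` relative to `a`, the correlation surface peak,
# and its z-score against the rest of the surface.  `max_shift` (rows,
# cols) restricts the peak search to a wrapped band of admissible shifts.
phase_correlate <- function(a, b, max_shift = c(Inf, Inf)) {
  stopifnot(all(dim(a) == dim(b)))
  A <- fft(a); B <- fft(b)
  R <- A * Conj(B)
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(fft(R, inverse = TRUE)) / length(R)
  wrapped <- function(n) { s <- seq_len(n) - 1; s[s > n / 2] <- s[s > n / 2] - n; s }
  ok_row <- abs(wrapped(nrow(r))) <= max_shift[1]
  ok_col <- abs(wrapped(ncol(r))) <= max_shift[2]
  rs <- r
  rs[!ok_row, ] <- -Inf; rs[, !ok_col] <- -Inf
  pk <- which.max(rs)
  ij <- arrayInd(pk, dim(r))
  H <- nrow(r); W <- ncol(r)
  # parabolic sub-pixel interpolation around the peak (wrapped neighbors)
  sub <- function(i, n, get) {
    ym <- get(((i - 2) %% n) + 1); y0 <- get(i); yp <- get(i %% n + 1)
    den <- ym - 2 * y0 + yp
    if (abs(den) < 1e-15) 0 else 0.5 * (ym - yp) / den
  }
  dy <- sub(ij[1], H, function(i) r[i, ij[2]])
  dx <- sub(ij[2], W, function(j) r[ij[1], j])
  shift_y <- ij[1] - 1 + dy; shift_x <- ij[2] - 1 + dx
  if (shift_y > H / 2) shift_y <- shift_y - H
  if (shift_x > W / 2) shift_x <- shift_x - W
  mu <- mean(r); s <- sd(r)
  list(shift = c(shift_y, shift_x), peak = r[pk],
       zscore = (r[pk] - mu) / max(s, 1e-15))
}

# Log-polar resampling of a (fftshifted) spectrum magnitude: rows span
# angle in [0, pi), columns log-radius in [log rmin, log rmax].
logpolar_sample <- function(m, n_angles = 540L, n_radii = 512L, rmin = 2) {
  H <- nrow(m); W <- ncol(m)
  cy <- H %/% 2 + 1; cx <- W %/% 2 + 1
  rmax <- min(H, W) / 2 - 1
  theta <- (seq_len(n_angles) - 1) / n_angles * pi
  logr <- seq(log(rmin), log(rmax), length.out = n_radii)
  rr <- exp(logr)
  yy <- cy + outer(sin(theta), rr)
  xx <- cx + outer(cos(theta), rr)
  out <- matrix(bilinear_sample(m, yy, xx), n_angles, n_radii)
  attr(out, "dlogr") <- logr[2] - logr[1]
  attr(out, "dtheta") <- pi / n_angles
  out
}

spectrum_mag <- function(img) {
  img <- img - mean(img)
  img <- img * hann2(nrow(img), ncol(img))
  F <- fftshift2(Mod(fft(img)))
  # Reddy-Chatterji high-pass to kill the DC-centred energy ridge
  xi <- (seq_len(nrow(F)) - (nrow(F) %/% 2 + 1)) / nrow(F)
  eta <- (seq_len(ncol(F)) - (ncol(F) %/% 2 + 1)) / ncol(F)
  X <- outer(cos(pi * xi), cos(pi * eta))
  F * ((1 - X) * (2 - X))
}

pad_to <- function(m, H, W) {
  out <- matrix(0, H, W)
  y0 <- (H - nrow(m)) %/% 2; x0 <- (W - ncol(m)) %/% 2
  out[y0 + seq_len(nrow(m)), x0 + seq_len(ncol(m))] <- m
  out
}

# Inverse-mapped similarity warp about the image center (scale > 1 grows
# features), bilinear, zero fill.
warp_similarity <- function(img, scale, rot_deg, out_dim = dim(img)) {
  H <- out_dim[1]; W <- out_dim[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  icy <- (nrow(img) + 1) / 2; icx <- (ncol(img) + 1) / 2
  th <- rot_deg * pi / 180
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sy <- (cos(th) * yy - sin(th) * xx) / scale + icy
  sx <- (sin(th) * yy + cos(th) * xx) / scale + icx
  bilinear_sample(img, sy, sx)
}

#' Estimate the linear expansion ratio by image registration
#'
#' Works on the maximum-intensity projections.  Scale and rotation are
#' recovered by phase correlation of the log-polar-resampled Fourier
#' magnitudes (rotation limited to +/- 30 degrees), the scale is refined by
#' maximizing the phase-correlation peak of the similarity-warped pre
#' image, and the translation comes from a final phase correlation.  The
#' ratio combines the pixel-domain scale with the pixel-size metadata:
#' `ratio = scale * post$pixel_size_xy / pre$pixel_size_xy`.
#'
#' @param pre,post [image_volume()]s of the same field before and after
#'   expansion (overlapping structure required).
#' @param min_zscore registration-significance threshold on the final
#'   correlation peak; below it the estimate is refused rather than
#'   silently wrong.
#' @return class `expansion_estimate`: `ratio`, `transform`
#'   (scale/rotation/translation), `residual_rms_nm`, `peak_zscore`.
#' @export
estimate_expansion_ratio <- function(pre, post, min_zscore = 8) {
  stopifnot(inherits(pre, "vista_volume"), inherits(post, "vista_volume"))
  a <- max_intensity_projection(pre)
  b <- max_intensity_projection(post)
  # bring both projections to comparable, moderate sizes: keeps the Fourier
  # log-polar grids overlapping and the refinement cheap; the per-image
  # factors are undone in the final ratio
  fa <- max(1, 2^ceiling(log2(max(dim(a)) / 256)))
  fb <- max(1, 2^ceiling(log2(max(dim(b)) / 256)))
  if (fa > 1) a <- resize_bilinear(a, nrow(a) %/% fa, ncol(a) %/% fa)
  if (fb > 1) b <- resize_bilinear(b, nrow(b) %/% fb, ncol(b) %/% fb)
  # light smoothing suppresses the broadband shot-noise floor that would
  # otherwise dominate the high-frequency spectrum magnitudes
  a <- blur2d(a, 1); b <- blur2d(b, 1)
  n <- nextn(max(dim(a), dim(b)), 2)
  a2 <- pad_to(a, n, n); b2 <- pad_to(b, n, n)
  la <- logpolar_sample(spectrum_mag(a2))
  lb <- logpolar_sample(spectrum_mag(b2))
  at <- attributes(la)
  # log-compress and remove the per-radius mean: the generic radial decay
  # of image spectra is common to both and would otherwise pin the
  # correlation to zero scale shift
  lnorm <- function(m) { m <- log1p(m); sweep(m, 2, colMeans(m)) }
  la <- lnorm(la); lb <- lnorm(lb)
  # admissible band: rotation within +/-35 deg, residual scale (after the
  # size normalization above) within a factor 2.5
  pc <- phase_correlate(la, lb,
                        max_shift = c(35 / 180 * nrow(la),
                                      log(2.5) / at$dlogr))
  # features scaled up by s shrink the magnitude spectrum radially by 1/s:
  # the log-polar images shift by log(s) along log-radius
  scale0 <- exp(pc$shift[2] * at$dlogr)
  rot0 <- -pc$shift[1] * at$dtheta * 180 / pi
  if (rot0 > 90) rot0 <- rot0 - 180
  if (abs(rot0) > 30)
    stop("registration failure: recovered rotation ", round(rot0, 1),
         " degrees exceeds the +/-30 degree search range")
  # refine the log-polar scale by maximizing the image correlation of the
  # translation-aligned warp: smooth in scale, unlike the whitened
  # phase-correlation peak height
  circ_shift <- function(m, s) {
    s <- round(s) %% dim(m)
    if (s[1] > 0) m <- m[c((s[1] + 1):nrow(m), 1:s[1]), , drop = FALSE]
    if (s[2] > 0) m <- m[, c((s[2] + 1):ncol(m), 1:s[2]), drop = FALSE]
    m
  }
  score <- function(ls) {
    w <- warp_similarity(a2, exp(ls), rot0)
    pc <- phase_correlate(b2, w)
    stats::cor(as.vector(b2), as.vector(circ_shift(w, pc$shift)))
  }
  grid <- log(scale0) + seq(-0.03, 0.03, by = 0.005)
  sc <- vapply(grid, score, 0)
  i <- which.max(sc)
  if (i > 1 && i < length(grid)) {   # parabolic sub-grid interpolation
    den <- sc[i - 1] - 2 * sc[i] + sc[i + 1]
    off <- if (abs(den) > 1e-12) 0.5 * (sc[i - 1] - sc[i + 1]) / den else 0
    scale <- exp(grid[i] + off * 0.005)
  } else scale <- exp(grid[i])
  warped <- warp_similarity(a2, scale, rot0)
  fin <- phase_correlate(b2, warped)
  if (fin$zscore < min_zscore)
    stop("registration failure: correlation peak z-score ",
         round(fin$zscore, 1), " below the significance threshold ",
         min_zscore)
  ratio <- scale * (fb / fa) * post$pixel_size_xy / pre$pixel_size_xy
  aligned <- warp_displace(warped, matrix(-fin$shift[1], n, n),
                           matrix(-fin$shift[2], n, n))
  res <- block_residual_rms(aligned, b2, post$pixel_size_xy)
  structure(list(ratio = ratio,
                 transform = list(scale = scale, rotation_deg = rot0,
                                  translation_px = fin$shift),
                 residual_rms_nm = res, peak_zscore = fin$zscore),
            class = "expansion_estimate")
}

# Intensity-weighted RMS of per-block displacements after alignment.
block_residual_rms <- function(a, b, pixel_size, nblocks = 4L) {
  H <- nrow(a); bs <- H %/% nblocks
  disp <- c(); wts <- c()
  for (i in seq_len(nblocks)) for (j in seq_len(nblocks)) {
    ys <- ((i - 1) * bs + 1):(i * bs); xs <- ((j - 1) * bs + 1):(j * bs)
    ab <- a[ys, xs]; bb <- b[ys, xs]
    w <- sum(ab^2) * sum(bb^2)
    if (w <= 0) next
    pc <- phase_correlate(bb, ab)
    disp <- c(disp, sum(pc$shift^2)); wts <- c(wts, sqrt(w))
  }
  if (length(disp) == 0) return(NA_real_)
  sqrt(sum(disp * wts) / sum(wts)) * pixel_size
}

#' @export
print.expansion_estimate <- function(x, ...) {
  cat(sprintf("<expansion_estimate> ratio %.3f (scale %.3f, rot %.2f deg, peak z %.1f, residual %.0f nm)\n",
              x$ratio, x$transform$scale, x$transform$rotation_deg,
              x$peak_zscore, x$residual_rms_nm))
  invisible(x)
}

#' Quantify protein retention with expansion-corrected scaling
#'
#' Linear expansion by `E` spreads retained molecules over `E^3` the
#' volume, so per-voxel intensities of conserved signal dilute by `E^3`.
#' Retention compares structure-masked mean intensities after undoing that
#' dilution:
#' `retention = mean_expanded * E^3 / mean_original`,
#' `loss_percent = 100 * (1 - retention)`.
#'
#' @param expanded,original [image_volume()]s (background-subtracted).
#' @param mask_expanded,mask_original logical masks matching each volume
#'   (3-D) or its projection (2-D).
#' @param ratio linear expansion factor (>= 1).
#' @return class `retention_report` with the fields above.
#' @export
measure_retention <- function(expanded, original, mask_expanded,
                              mask_original, ratio) {
  stopifnot(inherits(expanded, "vista_volume"),
            inherits(original, "vista_volume"), ratio >= 1)
  masked_mean <- function(v, mask) {
    img <- if (length(dim(mask)) == 2L) max_intensity_projection(v) else v$voxels
    if (!any(mask)) stop("empty mask")
    mean(img[mask])
  }
  me <- masked_mean(expanded, mask_expanded)
  mo <- masked_mean(original, mask_original)
  if (mo <= 0) stop("mean original intensity is not positive; ",
                    "check background subtraction")
  dilution <- ratio^3
  retention <- me * dilution / mo
  structure(list(mean_expanded = me, mean_original = mo,
                 expansion_ratio = ratio, dilution_factor = dilution,
                 retention_fraction = retention,
                 loss_percent = 100 * (1 - retention)),
            class = "retention_report")
}

#' @export
print.retention_report <- function(x, ...) {
  cat(sprintf("<retention_report> retention %.3f (loss %.1f%%) at %gx expansion (dilution %g)\n",
              x$retention_fraction, x$loss_percent, x$expansion_ratio,
              x$dilution_factor))
  invisible(x)
}

#' Segment protein-dense cells in a CH3 image
#'
#' Otsu threshold on the Gaussian-smoothed maximum-intensity projection,
#' holes filled, objects below `min_area` pixels removed.
#'
#' @param v an [image_volume()] of the CH3 channel.
#' @param smooth_sigma_px Gaussian smoothing sigma in pixels.
#' @param min_area minimum object area in pixels.
#' @return logical `(y, x)` mask.
#' @export
segment_cells <- function(v, smooth_sigma_px = 2, min_area = 100) {
  stopifnot(inherits(v, "vista_volume"))
  img <- max_intensity_projection(v)
  sm <- blur2d(img, smooth_sigma_px)
  rng <- range(sm)
  if (diff(rng) <= 0) stop("uniform image: no foreground to segment")
  norm <- (sm - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > thr
  mask <- EBImage::fillHull(mask * 1) > 0.5
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  mask <- matrix(lab %in% keep, nrow(img), ncol(img))
  if (!any(mask)) stop("no objects above the minimum area: empty mask")
  message(sprintf("segment_cells: %d object(s), areas %s px",
                  length(keep), paste(sizes[keep], collapse = ", ")))
  mask
}
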