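# Label-free prediction pipeline: preprocessing (rolling-ball background
# subtraction + percentile normalization), patch-based U-Net training with
# Adam on mean squared error, and tiled whole-image inference.

#' Training configuration
#'
#' Defaults follow the published regime (128 px patches, batch 32, Adam at
#' learning rate 0.001, MSE loss, 1:3 test:train split); `steps` defaults
#' to a desk-scale 2,000 optimizer steps — the full-scale regime is 50,000.
#' `depth` and `base_channels` size the encoder-decoder so desk-scale
#' models can shrink.
#'
#' @param patch_size square patch side in px; must be divisible by
#'   `2^depth`.
#' @param batch_size patches per optimizer step.
#' @param learning_rate Adam learning rate.
#' @param steps number of optimizer steps (one batch each).
#' @param test_fraction fraction of images held out for testing.
#' @param seed RNG seed controlling split, weight init and patch sampling.
#' @param depth number of pooling levels.
#' @param base_channels feature channels at the top level.
#' @param rolling_ball_radius background-subtraction ball radius, px.
#' @param norm_probs percentile window (fractions) for intensity
#'   normalization after background subtraction.
#' @export
train_config <- function(patch_size = 128L, batch_size = 32L,
                         learning_rate = 1e-3, steps = 2000L,
                         test_fraction = 0.25, seed = 0L, depth = 4L,
                         base_channels = 32L, rolling_ball_radius = 50L,
                         norm_probs = c(0.01, 0.999)) {
  stopifnot(test_fraction > 0, test_fraction < 1, batch_size >= 1,
            patch_size >= 2^depth, depth >= 1, base_channels >= 1,
            steps >= 1, learning_rate > 0)
  if (patch_size %% 2^depth != 0)
    stop("patch_size must be divisible by 2^depth")
  structure(list(patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, steps = as.integer(steps),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 rolling_ball_radius = as.integer(rolling_ball_radius),
                 norm_probs = norm_probs),
            class = "train_config")
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale opening of the image
#' against a ball-shaped (non-flat) structuring element of the given
#' radius — erosion then dilation with height `sqrt(r^2 - d^2)` — and
#' subtracts it, clipping at zero.
#'
#' @param img 2-D numeric matrix.
#' @param radius ball radius in pixels (>= 1, smaller than the image).
#' @return background-subtracted matrix, same shape.
#' @export
rolling_ball_subtract <- function(img, radius) {
  stopifnot(is.matrix(img))
  radius <- as.integer(radius)
  if (radius < 1) stop("radius must be >= 1")
  if (radius >= min(dim(img)))
    stop("rolling-ball radius must be smaller than the image")
  bg <- cpp_ball_dilate(cpp_ball_erode(img, radius), radius)
  pmax(img - bg, 0)
}

# Shared preprocessing for training and inference: rolling-ball background
# subtraction followed by per-slice percentile windowing to [0, 1].
preprocess_slice <- function(img, radius, probs) {
  x <- rolling_ball_subtract(img, radius)
  win <- quantile(x, probs, names = FALSE)
  rng <- win[2] - win[1]
  if (rng <= 0) return(x * 0)
  pmin(pmax((x - win[1]) / rng, 0), 1)
}

#' Build a paired SRS/fluorescence training dataset
#'
#' z-slices of each volume pair become pixel-registered 2-D training
#' pairs.  Both channels are rolling-ball background subtracted and
#' percentile-normalized per slice.  The train/test split is assigned
#' randomly per *volume* (never per patch or slice), at `test_fraction`.
#'
#' @param srs list of input CH3 [image_volume()]s.
#' @param target list of matching fluorescence [image_volume()]s.
#' @param config a [train_config()].
#' @return class `paired_dataset`: preprocessed slice pairs with split
#'   labels, plus the preprocessing parameters.
#' @export
build_dataset <- function(srs, target, config) {
  if (inherits(srs, "vista_volume")) srs <- list(srs)
  if (inherits(target, "vista_volume")) target <- list(target)
  stopifnot(inherits(config, "train_config"))
  if (length(srs) != length(target)) stop("pairing error: list lengths differ")
  if (length(srs) < 4) stop("split error: need at least 4 paired images")
  pairs <- list()
  for (i in seq_along(srs)) {
    if (!all(dim(srs[[i]]$voxels) == dim(target[[i]]$voxels)))
      stop("pairing error: volume ", i, " shapes differ")
    for (z in seq_len(dim(srs[[i]]$voxels)[1])) {
      pairs[[length(pairs) + 1L]] <- list(
        x = preprocess_slice(srs[[i]]$voxels[z, , ],
                             config$rolling_ball_radius, config$norm_probs),
        y = preprocess_slice(target[[i]]$voxels[z, , ],
                             config$rolling_ball_radius, config$norm_probs),
        image = i)
    }
  }
  n_img <- length(srs)
  n_test <- max(1L, round(config$test_fraction * n_img))
  test_ids <- with_seed(config$seed, sample.int(n_img, n_test))
  for (k in seq_along(pairs))
    pairs[[k]]$split <- if (pairs[[k]]$image %in% test_ids) "test" else "train"
  structure(list(pairs = pairs, n_images = n_img, test_images = test_ids,
                 rolling_ball_radius = config$rolling_ball_radius,
                 norm_probs = config$norm_probs,
                 target_label = target[[1]]$channel_label),
            class = "paired_dataset")
}

# ---- weights ---------------------------------------------------------------

# Layer shapes in the fixed order the C++ forward pass consumes:
# encoder double convs (top down), bottleneck, decoder double convs
# (bottom up), final 1x1 linear conv.
unet_layer_shapes <- function(depth, base, in_ch = 1L) {
  shapes <- list()
  ch_in <- in_ch
  for (d in seq_len(depth)) {
    ch_out <- base * 2^(d - 1)
    shapes <- c(shapes, list(c(9 * ch_in, ch_out), c(9 * ch_out, ch_out)))
    ch_in <- ch_out
  }
  ch_out <- base * 2^depth
  shapes <- c(shapes, list(c(9 * ch_in, ch_out), c(9 * ch_out, ch_out)))
  for (d in rev(seq_len(depth))) {
    ch_skip <- base * 2^(d - 1)
    ch_up <- base * 2^d
    shapes <- c(shapes, list(c(9 * (ch_skip + ch_up), ch_skip),
                             c(9 * ch_skip, ch_skip)))
  }
  c(shapes, list(c(base, 1L)))   # 1x1 conv: rows = in channels
}

init_unet_weights <- function(depth, base, seed) {
  shapes <- unet_layer_shapes(depth, base)
  with_seed(seed, lapply(shapes, function(s) {
    list(W = matrix(rnorm(s[1] * s[2], sd = sqrt(2 / s[1])), s[1], s[2]),
         b = numeric(s[2]))
  }))
}

#' Train a U-Net to predict a fluorescence channel from the CH3 channel
#'
#' Samples batches of random patch positions uniformly over the training
#' images and minimizes mean squared error with Adam for `config$steps`
#' optimizer steps.  Fully seeded: identical dataset, config and seed give
#' an identical loss trace.
#'
#' @param ds a [build_dataset()] result.
#' @param config a [train_config()].
#' @return class `vista_model`: weights, architecture/normalization
#'   contract, predicted channel label, and the training-loss trace.
#' @export
train_unet <- function(ds, config) {
  stopifnot(inherits(ds, "paired_dataset"), inherits(config, "train_config"))
  train_pairs <- Filter(function(p) p$split == "train", ds$pairs)
  if (length(train_pairs) == 0) stop("no training images")
  P <- config$patch_size
  hw <- dim(train_pairs[[1]]$x)
  if (P > min(hw)) stop("patch_size exceeds the training image size")
  weights <- init_unet_weights(config$depth, config$base_channels,
                               config$seed)
  m <- lapply(weights, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- lapply(weights, function(l) list(W = l$W * 0, b = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(config$steps)
  with_seed(config$seed + 1L, {
    for (step in seq_len(config$steps)) {
      xb <- vector("list", config$batch_size)
      yb <- vector("list", config$batch_size)
      for (k in seq_len(config$batch_size)) {
        p <- train_pairs[[sample.int(length(train_pairs), 1)]]
        y0 <- sample.int(nrow(p$x) - P + 1L, 1)
        x0 <- sample.int(ncol(p$x) - P + 1L, 1)
        xb[[k]] <- p$x[y0:(y0 + P - 1L), x0:(x0 + P - 1L)]
        yb[[k]] <- p$y[y0:(y0 + P - 1L), x0:(x0 + P - 1L)]
      }
      lg <- cpp_unet_loss_grad(weights, xb, yb, config$depth)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at step ", step)
      trace[step] <- lg$loss
      corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
      for (l in seq_along(weights)) {
        g <- lg$grads[[l]]
        m[[l]]$W <- b1 * m[[l]]$W + (1 - b1) * g$W
        m[[l]]$b <- b1 * m[[l]]$b + (1 - b1) * g$b
        v[[l]]$W <- b2 * v[[l]]$W + (1 - b2) * g$W^2
        v[[l]]$b <- b2 * v[[l]]$b + (1 - b2) * g$b^2
        weights[[l]]$W <- weights[[l]]$W -
          config$learning_rate * (m[[l]]$W / corr1) /
          (sqrt(v[[l]]$W / corr2) + eps)
        weights[[l]]$b <- weights[[l]]$b -
          config$learning_rate * (m[[l]]$b / corr1) /
          (sqrt(v[[l]]$b / corr2) + eps)
      }
    }
  })
  structure(list(weights = weights, depth = config$depth,
                 base_channels = config$base_channels,
                 patch_size = config$patch_size,
                 rolling_ball_radius = ds$rolling_ball_radius,
                 norm_probs = ds$norm_probs,
                 channel_label = ds$target_label,
                 config = config, loss_trace = trace),
            class = "vista_model")
}

#' @export
print.vista_model <- function(x, ...) {
  cat(sprintf("<vista_model> predicts '%s'; depth %d, base %d, patch %d; final loss %.3g\n",
              x$channel_label, x$depth, x$base_channels, x$patch_size,
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

# Per-axis blending weights for overlapping tiles.  Weight is zero over a
# margin at tile edges interior to the image (so border-affected
# predictions never contribute), ramps smoothly, and is flat in the
# middle; tile sides flush with the image border stay flat to the edge,
# where tile and whole-image border behavior coincide.
tile_axis_weights <- function(T, left_flush, right_flush) {
  M <- floor(3 * T / 16)
  ramp <- max(floor(T / 8), 1)
  w <- rep(1, T)
  u <- seq_len(T) - 1
  left <- pmin(pmax((u - M) / ramp, 0), 1)
  right <- rev(left)
  w <- pmin(0.5 - 0.5 * cos(pi * left), 0.5 - 0.5 * cos(pi * right))
  if (left_flush) w[seq_len(T %/% 2)] <- 1
  if (right_flush) w[(T %/% 2 + 1):T] <- 1
  w
}

# Reflective index map 1..total -> 1..n (period 2n-2), so padding can
# exceed the source size.
reflect_idx <- function(n, total) {
  if (n == 1L) return(rep(1L, total))
  j <- (seq_len(total) - 1L) %% (2L * n - 2L)
  ifelse(j >= n, 2L * n - 2L - j, j) + 1L
}

reflect_pad <- function(m, bottom, right) {
  m[reflect_idx(nrow(m), nrow(m) + bottom),
    reflect_idx(ncol(m), ncol(m) + right), drop = FALSE]
}

# Tiled inference on one preprocessed slice: overlapping tiles at stride
# tile/2, blended by the smooth window above.
predict_slice_core <- function(model, x) {
  T <- model$patch_size
  H <- nrow(x); W <- ncol(x)
  if (H < T || W < T) {  # small inputs: reflective padding, never an error
    xp <- reflect_pad(x, max(0, T - H), max(0, T - W))
    return(predict_slice_core(model, xp)[seq_len(H), seq_len(W)])
  }
  S <- T %/% 2
  offs <- function(n) unique(c(seq(0L, n - T, by = S), n - T))
  acc <- matrix(0, H, W); wacc <- matrix(0, H, W)
  for (oy in offs(H)) for (ox in offs(W)) {
    tile <- x[oy + seq_len(T), ox + seq_len(T)]
    p <- cpp_unet_predict(model$weights, tile, model$depth)
    wy <- tile_axis_weights(T, oy == 0, oy == H - T)
    wx <- tile_axis_weights(T, ox == 0, ox == W - T)
    w2 <- outer(wy, wx)
    acc[oy + seq_len(T), ox + seq_len(T)] <-
      acc[oy + seq_len(T), ox + seq_len(T)] + p * w2
    wacc[oy + seq_len(T), ox + seq_len(T)] <-
      wacc[oy + seq_len(T), ox + seq_len(T)] + w2
  }
  acc / wacc
}

#' Predict a virtual fluorescence channel for a whole volume
#'
#' Each z-slice is preprocessed exactly as in training (enforced through
#' the normalization contract stored in the model) and passed through the
#' network with overlapping tiles (stride = tile/2) blended by a smooth
#' window.  The output channel label is `"v-<target>"` (virtual-staining
#' naming: v-lectin, v-DAPI, v-MAP2, v-NeuN).
#'
#' @param model a [train_unet()] model.
#' @param v input CH3 [image_volume()].
#' @return an [image_volume()] of the predicted channel.
#' @export
predict_channels <- function(model, v) {
  stopifnot(inherits(model, "vista_model"), inherits(v, "vista_volume"))
  out <- v$voxels * 0
  for (z in seq_len(dim(v$voxels)[1])) {
    x <- preprocess_slice(v$voxels[z, , ], model$rolling_ball_radius,
                          model$norm_probs)
    out[z, , ] <- predict_slice_core(model, x)
  }
  vol <- v
  vol$voxels <- out
  vol$channel_label <- paste0("v-", model$channel_label)
  vol
}

#' @rdname predict_channels
#' @param object,... S3 method arguments (`predict(model, v)`).
#' @export
predict.vista_model <- function(object, v, ...) predict_channels(object, v)

#' Save / load a trained model
#'
#' The model file is a single JSON document: architecture and
#' normalization contract in the header, weights as arrays.
#'
#' @param model a `vista_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vista_model"))
  obj <- list(
    header = list(depth = model$depth, base_channels = model$base_channels,
                  patch_size = model$patch_size,
                  rolling_ball_radius = model$rolling_ball_radius,
                  norm_probs = model$norm_probs,
                  channel_label = model$channel_label),
    weights = lapply(model$weights, function(l)
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- obj$header
  weights <- lapply(seq_len(nrow_or_len(obj$weights)), function(i) {
    wl <- if (is.data.frame(obj$weights)) lapply(obj$weights, `[[`, i)
          else obj$weights[[i]]
    list(W = matrix(unlist(wl$W), unlist(wl$dim)[1], unlist(wl$dim)[2]),
         b = as.numeric(unlist(wl$b)))
  })
  structure(list(weights = weights, depth = h$depth,
                 base_channels = h$base_channels, patch_size = h$patch_size,
                 rolling_ball_radius = h$rolling_ball_radius,
                 norm_probs = as.numeric(h$norm_probs),
                 channel_label = h$channel_label,
                 config = NULL, loss_trace = NA_real_),
            class = "vista_model")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
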