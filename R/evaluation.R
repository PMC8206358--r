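# Prediction accuracy: Pearson correlation against held-out ground truth,
# with the sparse-channel masking rule, and the accuracy-vs-ground-truth-
# noise robustness curve.

#' Pearson correlation coefficient between ground truth and prediction
#'
#' Implements `r = sum((x - xbar)(y - ybar)) /
#' sqrt(sum((x - xbar)^2) sum((y - ybar)^2))` directly; `x` is the
#' ground-truth pixel sequence, `y` the model output.  A constant argument
#' makes the coefficient undefined and raises an error rather than
#' returning a silent 0.
#'
#' @param x ground-truth pixel intensities.
#' @param y predicted pixel intensities, same length.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 samples")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    stop("undefined correlation: constant input sequence")
  sum(dx * dy) / sqrt(sxx * syy)
}

#' Evaluate a model on the held-out test images
#'
#' Computes per-image and pooled Pearson coefficients between ground truth
#' and prediction over the test split.  Under
#' `mask_rule = "signal_images_only"` (the sparse-channel rule: background
#' noise in images without genuine signal cannot be predicted), an image
#' participates only if the fraction of ground-truth pixels above its
#' robust threshold (`median + 3 * MAD`) exceeds `signal_threshold`.
#'
#' @param model a [train_unet()] model.
#' @param test a [build_dataset()] result (its `"test"` split is used).
#' @param mask_rule `"all_images"` or `"signal_images_only"`.
#' @param signal_threshold minimum above-threshold pixel fraction (default
#'   0.1%).
#' @return class `evaluation_report`: `per_image_r`, `pooled_r`,
#'   `mask_rule`, `n_images_used`, `noise_sigma`.
#' @export
evaluate_predictions <- function(model, test,
                                 mask_rule = c("all_images",
                                               "signal_images_only"),
                                 signal_threshold = 0.001) {
  stopifnot(inherits(model, "vista_model"), inherits(test, "paired_dataset"))
  mask_rule <- match.arg(mask_rule)
  pairs <- Filter(function(p) p$split == "test", test$pairs)
  if (length(pairs) == 0) stop("test split is empty")
  if (mask_rule == "signal_images_only") {
    has_signal <- vapply(pairs, function(p) {
      thr <- median(p$y) + 3 * mad(p$y)
      mean(p$y > thr) > signal_threshold
    }, TRUE)
    pairs <- pairs[has_signal]
    if (length(pairs) == 0)
      stop("no test image passes the signal mask; nothing to evaluate")
  }
  per_r <- numeric(0)
  gt <- list(); pr <- list()
  for (p in pairs) {
    yhat <- predict_slice_core(model, p$x)
    gt[[length(gt) + 1L]] <- as.vector(p$y)
    pr[[length(pr) + 1L]] <- as.vector(yhat)
    ri <- tryCatch(pearson(as.vector(p$y), as.vector(yhat)),
                   error = function(e) NA_real_)
    if (!is.na(ri)) per_r <- c(per_r, ri)
  }
  pooled <- pearson(unlist(gt), unlist(pr))
  structure(list(per_image_r = per_r, pooled_r = pooled,
                 mask_rule = mask_rule, n_images_used = length(pairs),
                 noise_sigma = 0),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> pooled r = %.4f over %d image(s) [%s]%s\n",
              x$pooled_r, x$n_images_used, x$mask_rule,
              if (x$noise_sigma > 0)
                sprintf(" at gt-noise sigma %g", x$noise_sigma) else ""))
  invisible(x)
}

#' Accuracy as a function of training ground-truth noise
#'
#' For each noise level, the *training* ground truth is degraded by
#' additive Gaussian noise of `sigma * sd(clean training targets)` (test
#' ground truth stays clean), the model is retrained from the same seed,
#' and the pooled Pearson r is evaluated.  Model accuracy decreases as
#' training ground truth gets noisier.
#'
#' @param ds a [build_dataset()] result.
#' @param config a [train_config()].
#' @param sigmas ascending noise levels, starting at 0, in units of the
#'   clean training-target standard deviation.
#' @param seed RNG seed for the noise draws.
#' @param mask_rule,signal_threshold passed to [evaluate_predictions()].
#' @return data frame with columns `sigma`, `pooled_r`.
#' @export
noise_robustness_curve <- function(ds, config, sigmas, seed = 1,
                                   mask_rule = "all_images",
                                   signal_threshold = 0.001) {
  stopifnot(inherits(ds, "paired_dataset"), inherits(config, "train_config"))
  if (is.unsorted(sigmas, strictly = TRUE) || sigmas[1] != 0)
    stop("sigmas must be strictly ascending and start at 0")
  train_idx <- which(vapply(ds$pairs, function(p) p$split == "train", TRUE))
  sd_clean <- sd(unlist(lapply(ds$pairs[train_idx], function(p) p$y)))
  out <- data.frame(sigma = sigmas, pooled_r = NA_real_)
  for (i in seq_along(sigmas)) {
    s <- sigmas[i]
    ds2 <- ds
    if (s > 0) {
      with_seed(seed + 101L * i, {
        for (k in train_idx) {
          p <- ds2$pairs[[k]]
          ds2$pairs[[k]]$y <- p$y +
            matrix(rnorm(length(p$y), sd = s * sd_clean), nrow(p$y))
        }
      })
    }
    model <- tryCatch(train_unet(ds2, config),
                      error = function(e)
                        stop("training failed at sigma ", s, ": ",
                             conditionMessage(e)))
    ev <- evaluate_predictions(model, ds2, mask_rule = mask_rule,
                               signal_threshold = signal_threshold)
    out$pooled_r[i] <- ev$pooled_r
  }
  out
}
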