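test_that("rolling-ball subtraction equals the sliding-ball oracle", {
  set.seed(3)
  img <- matrix(runif(64 * 64, 0, 10), 64, 64)
  expect_equal(rolling_ball_subtract(img, 8), rolling_ball_reference(img, 8))

  # flat background is removed entirely
  expect_equal(max(abs(rolling_ball_subtract(matrix(5, 70, 70), 8))), 0)

  # a small bright spot survives; its smooth surround goes to ~0
  im2 <- matrix(2, 120, 120); im2[60:62, 60:62] <- 12
  rb <- rolling_ball_subtract(im2, 50)
  expect_gt(max(rb), 10 * 0.95)
  expect_equal(max(rb[1:40, 1:40]), 0)

  expect_error(rolling_ball_subtract(img, 64), "smaller than the image")
  expect_error(rolling_ball_subtract(img, 0), ">= 1")
})

test_that("dataset building splits per image and survives degenerate targets", {
  vols <- fx_training_volumes()
  cfg <- identity_config()
  ds <- build_dataset(vols, vols, cfg)
  splits <- vapply(ds$pairs, function(p) p$split, "")
  expect_equal(sum(splits == "test"), 2)
  expect_equal(sum(splits == "train"), 6)

  # same seed, same split; another seed differs
  ds_b <- build_dataset(vols, vols, cfg)
  expect_identical(ds_b$test_images, ds$test_images)
  cfg2 <- cfg; cfg2$seed <- 99L
  expect_false(identical(build_dataset(vols, vols, cfg2)$test_images,
                         ds$test_images))

  # all-zero target normalizes to all-zero, no division blowup
  zeros <- lapply(vols, function(v) { v$voxels <- v$voxels * 0; v })
  dz <- build_dataset(vols, zeros, cfg)
  expect_true(all(vapply(dz$pairs, function(p) all(p$y == 0), TRUE)))

  expect_error(build_dataset(vols[1:3], vols[1:3], cfg), "at least 4")
  bad <- vols; bad[[2]]$voxels <- bad[[2]]$voxels[, 1:10, , drop = FALSE]
  expect_error(build_dataset(vols, bad, cfg), "shapes differ")
})

test_that("training is seeded, finite, and converges on the identity task", {
  model <- fx_identity_model()
  tr <- model$loss_trace
  expect_true(all(is.finite(tr)))
  # final 100-step moving average well below the early loss
  expect_lt(mean(utils::tail(tr, 100)), tr[100])

  # identical config + seed => identical loss trace
  cfg <- train_config(patch_size = 32, batch_size = 4, steps = 25, depth = 1,
                      base_channels = 4, rolling_ball_radius = 15, seed = 7)
  ds <- fx_identity_dataset()
  t1 <- train_unet(ds, cfg)$loss_trace
  t2 <- train_unet(ds, cfg)$loss_trace
  expect_identical(t1, t2)
})

test_that("a constant-zero target is learned to near-zero held-out error", {
  vols <- fx_training_volumes()
  zeros <- lapply(vols, function(v) { v$voxels <- v$voxels * 0; v })
  cfg <- train_config(patch_size = 32, batch_size = 4, steps = 60, depth = 1,
                      base_channels = 4, rolling_ball_radius = 15, seed = 1)
  ds <- build_dataset(vols, zeros, cfg)
  m <- train_unet(ds, cfg)
  test_pairs <- Filter(function(p) p$split == "test", ds$pairs)
  mses <- vapply(test_pairs, function(p)
    mean((vistar:::predict_slice_core(m, p$x) - p$y)^2), 0)
  expect_lt(max(mses), 1e-4)
})

test_that("test images cannot influence training", {
  vols <- fx_training_volumes()
  cfg <- train_config(patch_size = 32, batch_size = 4, steps = 20, depth = 1,
                      base_channels = 4, rolling_ball_radius = 15, seed = 3)
  ds <- build_dataset(vols, vols, cfg)
  ref <- train_unet(ds, cfg)
  poisoned <- ds
  for (k in seq_along(poisoned$pairs))
    if (poisoned$pairs[[k]]$split == "test") {
      poisoned$pairs[[k]]$x[] <- 1e6
      poisoned$pairs[[k]]$y[] <- -1e6
    }
  poi <- train_unet(poisoned, cfg)
  expect_identical(poi$weights, ref$weights)
})

test_that("tiled inference is deterministic and matches whole-image output", {
  w <- vistar:::init_unet_weights(2, 8, seed = 1)
  model <- structure(list(weights = w, depth = 2L, base_channels = 8L,
                          patch_size = 128L, rolling_ball_radius = 15L,
                          norm_probs = c(0.01, 0.999),
                          channel_label = "lectin"), class = "vista_model")
  set.seed(2)
  x <- vistar:::blur2d(matrix(runif(256 * 256), 256, 256), 2)
  tiled <- vistar:::predict_slice_core(model, x)
  untiled <- vistar:::cpp_unet_predict(w, x, 2L)
  expect_lt(max(abs(tiled - untiled)) / diff(range(untiled)), 1e-3)

  # bitwise determinism of repeated inference
  expect_identical(vistar:::predict_slice_core(model, x), tiled)

  # inputs smaller than one tile are reflect-padded, never an error
  small <- image_volume(matrix(runif(40 * 40, 0, 10), 40, 40), 497)
  out <- predict_channels(model, small)
  expect_equal(dim(out$voxels), c(1, 40, 40))
  expect_equal(out$channel_label, "v-lectin")
})

test_that("identity model reproduces its own input through predict()", {
  model <- fx_identity_model()
  v <- fx_training_volumes()[[1]]
  pred <- predict_channels(model, v)
  x <- vistar:::preprocess_slice(v$voxels[1, , ], model$rolling_ball_radius,
                                 model$norm_probs)
  expect_gt(pearson(as.vector(x), as.vector(pred$voxels[1, , ])), 0.99)
  expect_equal(pred$channel_label, paste0("v-", model$channel_label))
})

test_that("models round-trip through the JSON file format", {
  model <- fx_identity_model()
  f <- tempfile(fileext = ".json")
  save_model(model, f)
  m2 <- load_model(f)
  expect_equal(m2$depth, model$depth)
  expect_equal(m2$patch_size, model$patch_size)
  expect_equal(m2$channel_label, model$channel_label)
  v <- fx_training_volumes()[[2]]
  expect_equal(predict_channels(m2, v)$voxels,
               predict_channels(model, v)$voxels, tolerance = 1e-12)
})
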