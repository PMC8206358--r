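test_that("volume round-trips through float32 TIFF with all metadata", {
  # values on the float32 grid so storage is lossless
  vox <- array(sample(0:4095, 5 * 12 * 10, replace = TRUE) / 4096,
               c(5, 12, 10))
  v <- image_volume(vox, pixel_size_xy = 497, z_step = 1000,
                    channel_label = "CH3-2940",
                    expansion_state = "expanded", expansion_factor = 4.2)
  f <- tempfile(fileext = ".tif")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(v2$voxels, v$voxels)
  expect_identical(v2$expansion_factor, 4.2)
  expect_identical(v2$channel_label, "CH3-2940")
  expect_identical(v2$pixel_size_xy, 497)
  expect_identical(v2$z_step, 1000)
  expect_identical(v2$expansion_state, "expanded")
})

test_that("reading honors sidecar metadata and rejects RGB pages", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0, 6, 6), f, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_xy = 100), paste0(tools::file_path_sans_ext(f), ".json"),
                       auto_unbox = TRUE)
  v <- read_volume(f)
  expect_equal(dim(v$voxels), c(1, 6, 6))
  expect_true(all(v$voxels == 0))
  expect_equal(v$pixel_size_xy, 100)

  frgb <- tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(4, 4, 3)), frgb)
  expect_error(read_volume(frgb), "page 1")
  expect_error(read_volume(tempfile(fileext = ".tif")), "cannot read")
})

test_that("16-bit integer pages are promoted without rescaling", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(c(0, 1000, 40000, 65535) / 65535, 2, 2), f,
                  bits.per.sample = 16L)
  v <- read_volume(f, pixel_size_xy = 100, z_step = 1000)
  expect_setequal(as.vector(v$voxels), c(0, 1000, 40000, 65535))
})

test_that("volume validation enforces the metadata invariants", {
  expect_error(image_volume(matrix(c(1, NA), 1, 2), 100), "finite")
  expect_error(image_volume(matrix(0, 2, 2), -5), "pixel_size_xy")
  expect_error(image_volume(matrix(0, 2, 2), 100, expansion_state = "expanded",
                            expansion_factor = 0.5), ">= 1")
  expect_error(image_volume(matrix(0, 2, 2), 100, expansion_factor = 4),
               "only meaningful")
})

test_that("maximum intensity projection matches a brute-force per-pixel max", {
  v1 <- image_volume(matrix(1:9, 3, 3), 100)
  expect_identical(max_intensity_projection(v1), matrix(1:9, 3, 3) * 1.0)
  # idempotent on its own single-slice result
  m <- max_intensity_projection(v1)
  expect_identical(max_intensity_projection(image_volume(m, 100)), m)

  two <- array(0, c(2, 2, 2))
  two[1, , ] <- c(0, 2, 1, 0); two[2, , ] <- c(3, 0, 0, 4)
  expect_identical(max_intensity_projection(image_volume(two, 1)),
                   matrix(c(3, 2, 1, 4), 2, 2))

  set.seed(1)
  vox <- array(rnorm(10 * 7 * 6), c(10, 7, 6))
  ref <- matrix(0, 7, 6)
  for (y in 1:7) for (x in 1:6) ref[y, x] <- max(vox[, y, x])
  expect_equal(max_intensity_projection(image_volume(vox, 1)), ref)
  # invariant under z-slice permutation
  perm <- vox[sample(10), , , drop = FALSE]
  expect_equal(max_intensity_projection(image_volume(perm, 1)), ref)
})

test_that("channel merging tints, rescales, and clips additively", {
  img <- matrix(runif(64, 10, 20), 8, 8)
  white <- merge_channels(list(img), "white")
  resc <- (img - min(img)) / diff(range(img))
  expect_equal(white[, , 1], resc)
  expect_equal(white[, , 2], resc)

  a <- matrix(0, 8, 8); a[1:4, ] <- 1
  b <- matrix(0, 8, 8); b[5:8, ] <- 1
  rg <- merge_channels(list(a, b), c("red", "green"))
  # disjoint supports: no pixel carries both red and green
  expect_equal(max(rg[, , 1] * rg[, , 2]), 0)

  set.seed(2)
  chans <- lapply(1:6, function(i) matrix(runif(64), 8, 8))
  cols <- c("red", "green", "blue", "cyan", "magenta", "yellow")
  out <- merge_channels(chans, cols)
  ref <- array(0, c(8, 8, 3))
  for (i in 1:6) {
    lo <- min(chans[[i]]); hi <- max(chans[[i]])
    tint <- as.numeric(grDevices::col2rgb(cols[i])) / 255
    for (y in 1:8) for (x in 1:8) for (k in 1:3)
      ref[y, x, k] <- ref[y, x, k] + (chans[[i]][y, x] - lo) / (hi - lo) * tint[k]
  }
  expect_equal(out, pmin(ref, 1))

  expect_error(merge_channels(list(a, matrix(0, 4, 4)), c("red", "green")),
               "shape")
})

test_that("analysis reports serialize losslessly", {
  rep <- analysis_report("retention",
                         payload = list(loss_percent = 79.03125,
                                        dilution_factor = 64),
                         provenance = list(seed = 7L, input = "phantom"))
  f <- tempfile(fileext = ".json")
  write_report(rep, f)
  rep2 <- read_report(f)
  expect_equal(rep2$kind, "retention")
  expect_equal(rep2$payload$loss_percent, 79.03125)
  expect_equal(rep2$payload$dilution_factor, 64)
  expect_equal(rep2$provenance$seed, 7L)
})
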