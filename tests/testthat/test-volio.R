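test_that("slice stacks round-trip through 8-bit TIFF", {
  set.seed(1)
  arr <- array(round(runif(6 * 12 * 10) * 255) / 255, dim = c(6, 12, 10))
  v <- ct_volume(arr, 0.05, "test")
  dir <- file.path(tempdir(), "stack-rt")
  write_stack(v, dir)
  v2 <- read_stack(dir, "*.tif", spacing_mm = 0.05)
  expect_identical(dim(v2$data), dim(v$data))
  expect_equal(v2$data, v$data, tolerance = 1e-12)
  expect_equal(v2$spacing_mm, 0.05)
  unlink(dir, recursive = TRUE)
})

test_that("read_stack enforces its contract", {
  dir <- file.path(tempdir(), "stack-bad")
  dir.create(dir, showWarnings = FALSE)
  expect_error(read_stack(dir, "*.tif", 0.05), "no slices")
  tiff::writeTIFF(matrix(0.5, 4, 4), file.path(dir, "a_0001.tif"))
  v <- read_stack(dir, "*.tif", 0.05)
  expect_identical(dim(v$data), c(1L, 4L, 4L))
  tiff::writeTIFF(matrix(0.5, 5, 4), file.path(dir, "a_0002.tif"))
  expect_error(read_stack(dir, "*.tif", 0.05), "ragged stack")
  unlink(dir, recursive = TRUE)
})

test_that("downsampling pools blocks, truncates dims and scales spacing", {
  set.seed(2)
  arr <- array(runif(13 * 9 * 7), dim = c(13, 9, 7))
  v <- ct_volume(arr, 0.01286)
  d3 <- downsample(v, 3)
  expect_identical(dim(d3$data), c(4L, 3L, 2L))
  expect_equal(d3$spacing_mm, 0.03858)
  # block mean checked against direct computation
  expect_equal(d3$data[1, 1, 1], mean(arr[1:3, 1:3, 1:3]))
  expect_equal(d3$data[4, 3, 2], mean(arr[10:12, 7:9, 4:6]))
  expect_identical(downsample(v, 1), v)
  expect_error(downsample(v, 0), "positive integer")
})

test_that("downsampling a resolved shape changes its measured volume by under 2%", {
  sp <- 0.04
  r0 <- 1.25  # 62 voxels across
  n <- ceiling(2 * (r0 + 0.2) / sp)
  g <- ((1:n) - 0.5) * sp - (r0 + 0.2)
  occ <- pmin(1, pmax(0, 0.5 + (r0 - sqrt(outer(outer(g^2, g^2, "+"),
                                               g^2, "+"))) / sp))
  v <- ct_volume(array(occ, dim = c(n, n, n)), sp)
  vol1 <- sum(v$data >= 0.5) * sp^3
  d2 <- downsample(v, 2)
  vol2 <- sum(d2$data >= 0.5) * d2$spacing_mm^3
  expect_lt(abs(vol2 - vol1) / vol1, 0.02)
})

test_that("crop_to_mask obeys bounding-box arithmetic", {
  v <- ct_volume(array(runif(20^3), dim = c(20, 20, 20)), 0.1)
  m <- array(FALSE, dim = c(20, 20, 20))
  m[5, 5, 5] <- TRUE
  cr <- crop_to_mask(v, ct_mask(m, 0.1), margin_vox = 1)
  expect_identical(dim(cr$data), c(3L, 3L, 3L))
  full <- ct_mask(array(TRUE, dim = c(20, 20, 20)), 0.1)
  expect_identical(dim(crop_to_mask(v, full, 0)$data), dim(v$data))
  box <- array(FALSE, dim = c(20, 20, 20))
  box[6:15, 9:12, 8:13] <- TRUE  # 10 x 4 x 6 box
  cr2 <- crop_to_mask(v, ct_mask(box, 0.1), margin_vox = 2)
  expect_identical(dim(cr2$data), c(14L, 8L, 10L))
  expect_error(crop_to_mask(v, ct_mask(array(FALSE, dim = c(20, 20, 20)),
                                       0.1)), "empty mask")
})
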