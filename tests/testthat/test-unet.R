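test_that("network configuration validates patch geometry", {
  spec <- net_spec()
  expect_identical(spec$patch, c(32L, 128L, 128L))
  expect_identical(spec$stride, c(24L, 96L, 96L))
  expect_identical(spec$channels, c(16L, 32L, 48L, 64L, 96L))
  expect_error(net_spec(patch = c(30, 128, 128)), "divisible")
  expect_error(net_spec(stride = c(40, 96, 96)), "stride")
  expect_error(net_spec(channels = 1:3), "channels")
})

test_that("tile starts cover the volume with boundary clamping", {
  expect_identical(tile_starts(64, 32, 24), c(0L, 24L, 32L))
  expect_identical(tile_starts(256, 128, 96), c(0L, 96L, 128L))
  # 3 x 3 x 3 = 27 tiles for a (64, 256, 256) volume
  n_tiles <- length(tile_starts(64, 32, 24)) *
    length(tile_starts(256, 128, 96)) * length(tile_starts(256, 128, 96))
  expect_identical(n_tiles, 27L)
  expect_identical(tile_starts(32, 32, 24), 0L)
  expect_identical(tile_starts(20, 32, 24), 0L)
})

test_that("patch sampling is deterministic and pads small volumes", {
  ph <- small_seed()
  p1 <- sample_patches(ph$volume, ph$masks$kernel, 10, rng_seed = 3,
                       patch = c(16L, 48L, 48L))
  p2 <- sample_patches(ph$volume, ph$masks$kernel, 10, rng_seed = 3,
                       patch = c(16L, 48L, 48L))
  expect_identical(lapply(p1, `[[`, "corner"), lapply(p2, `[[`, "corner"))
  big <- sample_patches(ph$volume, ph$masks$kernel, 1, rng_seed = 1,
                        patch = c(128L, 128L, 128L))[[1]]
  expect_identical(dim(big$volume), c(128L, 128L, 128L))
  expect_true(anyNA(big$labels))  # padding is excluded from training
  expect_error(sample_patches(ph$volume, ph$masks$kernel, 0), "n must be")
})

test_that("an 8:2 split of 20 items gives 16 train and 4 test", {
  sp <- split_train_test(as.list(1:20), ratio = 0.8, rng_seed = 2)
  expect_length(sp$train, 16)
  expect_length(sp$test, 4)
  expect_setequal(c(unlist(sp$train), unlist(sp$test)), 1:20)
})

test_that("Dice and IoU satisfy their definitions and identity", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), dim = c(4, 1, 1))
  b <- array(c(FALSE, TRUE, TRUE, FALSE), dim = c(4, 1, 1))
  m <- dice_iou(a, b)
  expect_equal(unname(m["dice"]), 0.5)
  expect_equal(unname(m["iou"]), 1 / 3)
  expect_identical(unname(dice_iou(a, a)), c(1, 1))
  none <- array(FALSE, dim = c(4, 1, 1))
  expect_identical(unname(dice_iou(a, none)), c(0, 0))
  expect_identical(unname(dice_iou(none, none)), c(1, 1))
  expect_error(dice_iou(a, array(TRUE, dim = c(2, 1, 1))), "shape mismatch")
  # dice = 2 iou / (1 + iou) across random mask pairs
  set.seed(12)
  for (i in 1:25) {
    x <- array(runif(300) < 0.4, dim = c(10, 10, 3))
    y <- array(runif(300) < 0.4, dim = c(10, 10, 3))
    mm <- dice_iou(x, y)
    expect_equal(unname(mm["dice"]), 2 * mm[["iou"]] / (1 + mm[["iou"]]),
                 tolerance = 1e-12)
  }
})

test_that("the learned path segments held-out phantom kernels", {
  phs <- cached("voxelnet_phantoms", {
    pop <- default_population()
    pop$sd <- rep(0, nrow(pop))
    lapply(sample_specs(pop, 3, rng_seed = 99), make_seed,
           spacing_mm = 0.08, gt_areas = FALSE)
  })
  model <- train_voxel_segmenter(lapply(phs[1:2], `[[`, "volume"),
                                 lapply(phs[1:2], function(p) p$masks$kernel),
                                 n_patches = 200, epochs = 60, rng_seed = 4)
  pred <- infer_sliding(model, phs[[3]]$volume)
  expect_identical(dim(pred$data), dim(phs[[3]]$volume$data))
  expect_dice_at_least(pred, phs[[3]]$masks$kernel, 0.95)
})
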