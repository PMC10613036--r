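test_that("binarise-and-fill recovers solid objects", {
  ph <- small_seed()
  m <- binarize_fill(ph$volume, min_size_vox = 500)
  # the internal cavity must be filled: mask covers the whole seed
  expect_true(all(m$data[ph$masks$cavity$data]))
  expect_dice_at_least(m$data, ph$masks$seed$data, 0.99)

  # hollow sphere shell becomes a solid ball
  n <- 50
  g <- (1:n) - 25.5
  rr <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
  img <- array(0.1 + 0.7 * (rr < 18 & rr > 14), dim = c(n, n, n))
  mb <- binarize_fill(ct_volume(img, 0.1), min_size_vox = 100)
  expect_true(all(mb$data[rr < 14]))

  # pure noise leaves no object after speck removal
  set.seed(5)
  noise <- ct_volume(array(runif(40^3, 0, 0.2), dim = c(40, 40, 40)), 0.1)
  expect_error(binarize_fill(noise, min_size_vox = 1000), "no object")
})

test_that("watershed separates touching spheres near the midplane", {
  n <- c(40, 40, 64)
  cz <- 20.5; cy <- 20.5
  r <- 12
  cx1 <- 23.5; cx2 <- cx1 + 1.5 * r  # centres 1.5 r apart
  arr <- array(FALSE, dim = n)
  for (x in 1:n[3]) for (y in 1:n[2]) for (z in 1:n[1]) {
    d1 <- sqrt((z - cz)^2 + (y - cy)^2 + (x - cx1)^2)
    d2 <- sqrt((z - cz)^2 + (y - cy)^2 + (x - cx2)^2)
    arr[z, y, x] <- d1 < r || d2 < r
  }
  inst <- split_instances(ct_mask(arr, 0.1), min_peak_distance_mm = 1,
                          min_size_vox = 100)
  expect_identical(inst$count, 2L)
  # split plane within one voxel of the geometric midplane
  mid <- (cx1 + cx2) / 2
  lab <- inst$labels
  xs1 <- which(apply(lab == lab[21, 21, round(cx1)], 3, any))
  xs2 <- which(apply(lab == lab[21, 21, round(cx2)], 3, any))
  expect_lte(max(xs1), ceiling(mid) + 1)
  expect_gte(min(xs2), floor(mid) - 1)

  # a single sphere is a single instance
  one <- arr
  one[, , (round(cx1) + r):n[3]] <- FALSE
  inst1 <- split_instances(ct_mask(one, 0.1), min_peak_distance_mm = 1,
                           min_size_vox = 100)
  expect_identical(inst1$count, 1L)
})

test_that("scene instances match the generator and overlap ground truth", {
  specs <- lapply(1:3, function(i) small_spec(rng_seed = i + 10))
  sc <- make_scene(specs, spacing_mm = 0.08, min_gap_mm = 0.5, rng_seed = 9)
  m <- binarize_fill(sc$volume, min_size_vox = 500)
  inst <- split_instances(m, min_peak_distance_mm = 1.5,
                          min_size_vox = 500)
  expect_identical(inst$count, 3L)
  # match each instance to the ground-truth label it overlaps most
  for (k in 1:3) {
    gt_label <- which.max(vapply(1:3, function(g)
      sum(inst$labels == k & sc$labels == g), numeric(1)))
    expect_dice_at_least(inst$labels == k, sc$labels == gt_label, 0.99)
  }
  # re-running is bit-identical: no hidden randomness
  inst2 <- split_instances(m, min_peak_distance_mm = 1.5,
                           min_size_vox = 500)
  expect_identical(inst$labels, inst2$labels)
})

test_that("instance extraction implements the AND operation", {
  ph <- small_seed()
  m <- binarize_fill(ph$volume, min_size_vox = 500)
  inst <- split_instances(m, min_peak_distance_mm = 1)
  expect_error(extract_instance(ph$volume, inst, 5L), "unknown label")
  ex0 <- extract_instance(ph$volume, inst, 1L, margin_vox = 0L)
  bb <- inst$boxes[[1]]
  expect_identical(dim(ex0$volume$data), as.integer(bb[, "hi"] - bb[, "lo"] + 1L))
  expect_true(all(ex0$volume$data[!ex0$mask$data] == 0))
  expect_identical(sum(ex0$mask$data), inst$sizes[1])
})
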