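test_that("threshold path recovers kernel, coat and cavity on the standard phantom", {
  ph <- cached("mean_seed_006", make_seed(mean_spec(), spacing_mm = 0.06,
                                          gt_areas = FALSE))
  comp <- segment_components(masked_volume(ph), ph$masks$seed)
  expect_length(comp$flags, 0)
  expect_dice_at_least(comp$kernel_mask, ph$masks$kernel, 0.98)
  expect_dice_at_least(comp$coat_mask, ph$masks$coat, 0.95)
  expect_dice_at_least(comp$cavity_mask, ph$masks$cavity, 0.95)
  # volume conservation on the same voxel grid is exact
  expect_identical(sum(comp$seed_mask$data),
                   sum(comp$kernel_mask$data) + sum(comp$coat_mask$data) +
                     sum(comp$cavity_mask$data))
})

test_that("a cavity-free seed yields kernel = interior minus coat", {
  spec <- mean_spec(rng_seed = 8)
  spec$target_fullness <- NA
  ph <- cached("zerocav_006", make_seed(spec, spacing_mm = 0.06,
                                        gt_areas = FALSE))
  expect_identical(sum(ph$masks$cavity$data), 0L)
  comp <- segment_components(masked_volume(ph), ph$masks$seed)
  expect_dice_at_least(comp$kernel_mask, ph$masks$kernel, 0.98)
  expect_lte(sum(comp$cavity_mask$data), 0.005 * sum(comp$seed_mask$data))
})

test_that("shell splitting handles boundary cases", {
  ph <- small_seed()
  # kernel covering the whole seed leaves an empty shell
  sh <- segment_shell(masked_volume(ph), ph$masks$seed, ph$masks$seed)
  expect_identical(sum(sh$coat$data), 0L)
  expect_identical(sum(sh$cavity$data), 0L)
  expect_error(segment_shell(ph$volume, ph$masks$kernel, ph$masks$seed),
               "not contained")
})

test_that("a contrast-free object has no identifiable kernel", {
  set.seed(31)
  n <- 48
  g <- (1:n) - (n + 1) / 2
  rr <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
  msk <- array(rr < 20, dim = c(n, n, n))
  img <- array(0.1 + 0.7 * msk + rnorm(n^3, 0, 0.04), dim = c(n, n, n))
  img <- array(pmin(1, pmax(0, img)), dim = c(n, n, n))
  img[!msk] <- 0
  expect_error(segment_kernel(ct_volume(img, 0.1), ct_mask(msk, 0.1)),
               "kernel not found")
})

test_that("recovered kernel fraction increases with target fullness", {
  fr <- vapply(c(0.35, 0.42, 0.49, 0.56, 0.62), function(f) {
    spec <- mean_spec(rng_seed = 13)
    spec$target_fullness <- f
    ph <- make_seed(spec, spacing_mm = 0.08, gt_areas = FALSE)
    comp <- segment_components(masked_volume(ph), ph$masks$seed)
    sum(comp$kernel_mask$data) / sum(comp$seed_mask$data)
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("damage flags fire on constructed defects and stay quiet otherwise", {
  ph <- small_seed()
  comp_gt <- seed_components(ph$masks$seed, ph$masks$kernel, ph$masks$coat,
                             ph$masks$cavity)
  expect_length(flag_damage(comp_gt), 0)

  br <- cached("breached_small",
               make_breached_seed(small_spec(rng_seed = 3), 0.06,
                                  hole_radius_mm = 0.2))
  comp_br <- seed_components(br$masks$seed, br$masks$kernel, br$masks$coat,
                             br$masks$cavity)
  expect_true("coat_breach" %in% flag_damage(comp_br))

  # kernel split in two by a plane (reassigned to cavity to keep the
  # partition): fragmented-kernel analogue
  frag <- ph$masks
  k <- frag$kernel$data
  bb <- which(apply(k, 3, any))
  cut <- bb[round(length(bb) / 2)]
  plane <- array(FALSE, dim = dim(k))
  plane[, , cut:(cut + 1)] <- TRUE
  frag$cavity$data <- frag$cavity$data | (k & plane)
  frag$kernel$data <- k & !plane
  comp_fr <- seed_components(frag$seed, frag$kernel, frag$coat, frag$cavity)
  expect_true("fragmented_kernel" %in% flag_damage(comp_fr))
})

test_that("component containers assert the partition invariant", {
  ph <- small_seed()
  bad <- ph$masks$kernel
  bad$data <- bad$data | ph$masks$coat$data
  expect_error(seed_components(ph$masks$seed, bad, ph$masks$coat,
                               ph$masks$cavity), "overlap")
  expect_error(seed_components(ph$masks$seed, ph$masks$kernel,
                               ph$masks$coat,
                               ct_mask(array(FALSE, dim = dim(ph$masks$seed$data)),
                                       0.06)),
               "partition")
})
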