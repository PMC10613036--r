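test_that("population draws respect ranges, ordering and determinism", {
  specs <- sample_specs(default_population(), 102, rng_seed = 3)
  L <- vapply(specs, function(s) 2 * s$semi_axes_mm[1], numeric(1))
  expect_true(all(L >= 7.26 & L <= 11.16))
  lwt <- vapply(specs, function(s) seedct:::.spec_lwt(s), numeric(3))
  expect_true(all(lwt[1, ] >= lwt[2, ] & lwt[2, ] >= lwt[3, ]))
  specs2 <- sample_specs(default_population(), 102, rng_seed = 3)
  expect_identical(vapply(specs2, function(s) s$semi_axes_mm[1], numeric(1)),
                   vapply(specs, function(s) s$semi_axes_mm[1], numeric(1)))
  # degenerate population: zero SD makes every geometry identical
  pop0 <- default_population()
  pop0$sd <- rep(0, nrow(pop0))
  s0 <- sample_specs(pop0, 5, rng_seed = 1)
  geom <- vapply(s0, function(s) c(s$semi_axes_mm, s$coat_thickness_mm,
                                   s$target_fullness), numeric(5))
  expect_true(all(apply(geom, 1, function(r) diff(range(r)) == 0)))
  badpop <- default_population()
  badpop$sd[1] <- -1
  expect_error(sample_specs(badpop, 3), "non-negative")
})

test_that("sample means of generated lengths recover the configured mean", {
  specs <- sample_specs(default_population(), 102, rng_seed = 17)
  L <- vapply(specs, function(s) 2 * s$semi_axes_mm[1], numeric(1))
  expect_lt(abs(mean(L) - 9.22), 3 * 0.70 / sqrt(102))
})

test_that("cavity calibration hits the target fullness within 0.005", {
  spec <- small_spec(fullness = 0.54)
  cal <- calibrate_cavity(spec, spacing_mm = 0.06)
  expect_gte(cal$realized_fullness, 0.535)
  expect_lte(cal$realized_fullness, 0.545)
  # maximum feasible fullness: no cavity at all
  spec_max <- small_spec()
  spec_max$target_fullness <- NA
  cal_max <- calibrate_cavity(spec_max, spacing_mm = 0.06)
  expect_identical(cal_max$cavity_radius_mm, 0)
  spec_bad <- small_spec(fullness = 0.95)
  expect_error(calibrate_cavity(spec_bad, spacing_mm = 0.06),
               "fullness unreachable")
})

test_that("an axis-aligned ellipsoid spec realises its analytic dimensions", {
  spec <- seed_spec(semi_axes_mm = c(4.61, 2.70, 2.43),
                    coat_thickness_mm = 0.16, target_fullness = 0.54,
                    taper = 0, pinch = 0, rng_seed = 2)
  ph <- make_seed(spec, spacing_mm = 0.06, gt_areas = FALSE)
  gt <- ph$ground_truth
  expect_equal(gt$seed_length_mm, 9.22, tolerance = 1e-6)
  expect_equal(gt$seed_width_mm, 5.40, tolerance = 1e-6)
  expect_equal(gt$seed_thickness_mm, 4.86, tolerance = 1e-6)
})

test_that("noise-free rendering produces flat plateaus per component", {
  ii <- list(background = 0.1, cavity = 0.2, kernel = 0.8, coat = 0.8,
             noise_sd = 0)
  spec <- small_spec(intensities = ii, noise_sd = 0)
  ph <- make_seed(spec, spacing_mm = 0.06, gt_areas = FALSE)
  d <- dim(ph$volume$data)
  erode <- function(m) {
    out <- seedct:::cpp_erode6(m, as.integer(d))
    dim(out) <- d
    out & seedct:::cpp_erode6(out, as.integer(d))
  }
  for (comp in c("kernel", "coat", "cavity")) {
    core <- erode(ph$masks[[comp]]$data)
    if (!any(core)) next
    vals <- unique(ph$volume$data[core])
    expect_length(vals, 1)
    expect_equal(vals, ii[[comp]])
  }
})

test_that("component masks partition the seed and volumes are conserved", {
  ph <- small_seed()
  k <- ph$masks$kernel$data
  ct <- ph$masks$coat$data
  cv <- ph$masks$cavity$data
  s <- ph$masks$seed$data
  expect_false(any(k & ct) || any(k & cv) || any(ct & cv))
  expect_identical(k | ct | cv, s)
  gt <- ph$ground_truth
  expect_identical(gt$seed_volume_mm3,
                   gt$kernel_volume_mm3 + gt$coat_volume_mm3 +
                     gt$cavity_volume_mm3)
})

test_that("ground truth scales as s^3 for volumes and s^2 for areas", {
  s1 <- small_spec(noise_sd = 0)
  s2 <- small_spec(noise_sd = 0)
  sc <- 1.3
  s2$semi_axes_mm <- s1$semi_axes_mm * sc
  s2$coat_thickness_mm <- s1$coat_thickness_mm * sc
  ph1 <- make_seed(s1, spacing_mm = 0.06)
  ph2 <- make_seed(s2, spacing_mm = 0.06)
  expect_equal(ph2$ground_truth$seed_volume_mm3 /
                 ph1$ground_truth$seed_volume_mm3, sc^3, tolerance = 0.01)
  expect_equal(ph2$ground_truth$seed_surface_area_mm2 /
                 ph1$ground_truth$seed_surface_area_mm2, sc^2,
               tolerance = 0.02)
})

test_that("scenes place every seed with its own label", {
  specs <- lapply(1:3, function(i) small_spec(rng_seed = i))
  sc <- make_scene(specs, spacing_mm = 0.08, min_gap_mm = 0.5, rng_seed = 4)
  expect_identical(sort(unique(as.vector(sc$labels[sc$labels > 0]))), 1:3)
  expect_identical(nrow(sc$ground_truth), 3L)
  sc1 <- make_scene(specs[1], spacing_mm = 0.08, rng_seed = 4)
  expect_identical(max(sc1$labels), 1L)
  expect_error(make_scene(specs, spacing_mm = 0.08, min_gap_mm = 0.5,
                          rng_seed = 4, scene_size_mm = c(5, 5, 5)),
               "packing failed")
})
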