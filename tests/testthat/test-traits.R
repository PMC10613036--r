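sphere_field <- function(r0, sp, margin = 0.15) {
  n <- ceiling(2 * (r0 + margin) / sp)
  g <- ((1:n) - 0.5) * sp - (r0 + margin)
  rr <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
  array(pmin(1, pmax(0, 0.5 + (r0 - rr) / sp)), dim = c(n, n, n))
}

test_that("isosurface area and volume match closed forms for spheres", {
  r0 <- 1.25
  mesh <- mesh_from_field(sphere_field(r0, 0.04), 0.04)
  expect_true(mesh$watertight)
  expect_lt(abs(mesh$area_mm2 - 4 * pi * r0^2) / (4 * pi * r0^2), 0.02)
  expect_lt(abs(mesh$volume_mm3 - 4 / 3 * pi * r0^3) / (4 / 3 * pi * r0^3),
            0.02)
  # error decreases with refinement
  coarse <- mesh_from_field(sphere_field(r0, 0.08), 0.08)
  expect_lt(abs(mesh$area_mm2 - 4 * pi * r0^2),
            abs(coarse$area_mm2 - 4 * pi * r0^2) + 1e-9)
})

test_that("a single-voxel mask still meshes watertight", {
  m <- array(FALSE, dim = c(7, 7, 7))
  m[4, 4, 4] <- TRUE
  mesh <- mesh_from_mask(ct_mask(m, 0.1))
  expect_true(mesh$watertight)
  expect_gt(mesh$volume_mm3, 0)
})

test_that("Feret dimensions recover analytic extents", {
  spec <- seed_spec(semi_axes_mm = c(4.61, 2.70, 2.43),
                    coat_thickness_mm = 0.16, target_fullness = 0.54,
                    taper = 0, pinch = 0, rng_seed = 1)
  r <- seedct:::.render_seed(spec, 0.05)
  mesh <- mesh_from_field(r$O, 0.05, check_watertight = FALSE)
  fd <- feret_dims(mesh)
  expect_equal(unname(fd["length"]), 9.22, tolerance = 0.01)
  expect_equal(unname(fd["width"]), 5.40, tolerance = 0.01)
  expect_equal(unname(fd["thickness"]), 4.86, tolerance = 0.01)

  sph <- mesh_from_field(sphere_field(1.25, 0.05), 0.05,
                         check_watertight = FALSE)
  fs <- feret_dims(sph)
  expect_equal(unname(fs), rep(2.5, 3), tolerance = 0.02)
})

test_that("Feret length agrees with a dense direction-grid oracle on a cube", {
  m <- array(FALSE, dim = c(30, 30, 30))
  m[6:25, 6:25, 6:25] <- TRUE
  mesh <- mesh_from_mask(ct_mask(m, 0.1), check_watertight = FALSE)
  fd <- feret_dims(mesh)
  oracle <- feret_oracle(mesh$vertices)
  expect_equal(unname(fd["length"]), oracle, tolerance = 0.01)
  expect_true(fd["length"] >= fd["width"] &&
                fd["width"] >= fd["thickness"])
})

test_that("coat thickness estimator is accurate on analytic shells", {
  sp <- 0.04
  n <- ceiling(2 * 2.6 / sp)
  g <- ((1:n) - 0.5) * sp - 2.6
  r2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  shell <- array(r2 <= 2.50^2 & r2 > 2.34^2, dim = c(n, n, n))
  est <- avg_coat_thickness(ct_mask(shell, sp))
  expect_lt(abs(est - 0.16), 0.01)

  # flat slab: within half a voxel (odd voxel count; even counts carry an
  # extra ~0.1-voxel quantisation penalty because the medial plane falls
  # between voxel centres)
  slab <- array(FALSE, dim = c(40, 40, 40))
  slab[15:19, , ] <- TRUE  # 5 voxels = 0.20 mm at 0.04
  est_slab <- avg_coat_thickness(ct_mask(slab, sp))
  expect_lt(abs(est_slab - 0.20), 0.02)
  slab4 <- array(FALSE, dim = c(40, 40, 40))
  slab4[15:18, , ] <- TRUE  # 4 voxels = 0.16 mm
  expect_lt(abs(avg_coat_thickness(ct_mask(slab4, sp)) - 0.16), 0.6 * sp)

  # ellipsoidal shell of constant normal thickness 0.2 mm
  spec <- seed_spec(semi_axes_mm = c(4.0, 2.5, 2.0),
                    coat_thickness_mm = 0.2, target_fullness = 0.5,
                    taper = 0, pinch = 0)
  geo <- seedct:::.render_outer(spec, sp)
  esh <- array(geo$dn >= 0 & geo$dn < 0.2, dim = geo$dims)
  est_e <- avg_coat_thickness(ct_mask(esh, sp))
  expect_lt(abs(est_e - 0.2) / 0.2, 0.10)
  # cross-check estimator from volume and areas
  outer_mesh <- mesh_from_field(array(pmin(1, pmax(0, 0.5 + geo$dn / sp)),
                                      dim = geo$dims), sp,
                                check_watertight = FALSE)
  inner_mesh <- mesh_from_field(array(pmin(1, pmax(0, 0.5 + (geo$dn - 0.2) / sp)),
                                      dim = geo$dims), sp,
                                check_watertight = FALSE)
  alt <- coat_thickness_from_areas(sum(esh) * sp^3, outer_mesh$area_mm2,
                                   inner_mesh$area_mm2)
  expect_lt(abs(alt - 0.2) / 0.2, 0.10)
})

test_that("full trait extraction matches phantom ground truth", {
  ph <- cached("mean_seed_005", make_seed(mean_spec(rng_seed = 5), 0.05))
  comp <- segment_components(masked_volume(ph), ph$masks$seed)
  tr <- compute_traits(comp)
  gt <- ph$ground_truth
  tight <- c("seed_length_mm", "seed_width_mm", "seed_thickness_mm",
             "seed_volume_mm3", "kernel_volume_mm3", "seed_fullness")
  for (nm in tight)
    expect_lt(abs(tr[[nm]] - gt[[nm]]) / gt[[nm]], 0.03)
  loose <- c("seed_surface_area_mm2", "kernel_surface_area_mm2",
             "avg_coat_thickness_mm")
  for (nm in loose)
    expect_lt(abs(tr[[nm]] - gt[[nm]]) / gt[[nm]], 0.05)
  expect_true(tr$seed_length_mm >= tr$seed_width_mm &&
                tr$seed_width_mm >= tr$seed_thickness_mm)
  expect_equal(tr$seed_volume_mm3,
               tr$kernel_volume_mm3 + tr$coat_volume_mm3 +
                 tr$cavity_volume_mm3)
  # flagged seeds are refused
  comp$flags <- "coat_breach"
  expect_error(compute_traits(comp), "coat_breach")
})

test_that("evaluation indices are the exact defining ratios", {
  tr <- data.frame(seed_surface_area_mm2 = 148.51, coat_volume_mm3 = 23.99,
                   avg_coat_thickness_mm = 0.16, seed_thickness_mm = 4.86,
                   cavity_volume_mm3 = 10.33, kernel_volume_mm3 = 54.25,
                   seed_volume_mm3 = 100.34)
  idx <- compute_indices(tr)
  expect_equal(idx$coat_specific_surface_area, 148.51 / 23.99,
               tolerance = 1e-12)
  expect_equal(idx$coat_thickness_ratio, 0.16 / 4.86, tolerance = 1e-12)
  expect_equal(idx$seed_density_ratio, 10.33 / 54.25, tolerance = 1e-12)
  # magnitudes of the typical seed
  expect_equal(round(idx$coat_specific_surface_area, 3), 6.190)
  expect_equal(round(idx$coat_thickness_ratio, 4), 0.0329)
  expect_equal(round(idx$seed_density_ratio, 4), 0.1904)
  expect_equal(round(54.25 / 100.34, 4), 0.5407)
  tr$coat_volume_mm3 <- 0
  expect_error(compute_indices(tr), "zero denominator")
})
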