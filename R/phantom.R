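# Synthetic seed phantoms: tapered spindle-shaped shells with a kernel,
# a constant-thickness coat, and a polar cavity cap, rendered with
# partial-volume edges and additive Gaussian noise, with exact ground truth.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Truncated normal draws via inverse-CDF (exact; degenerates to the mean
# when sd = 0).
.truncnorm <- function(n, mean, sd, lo, hi) {
  if (sd < 0) stop("SD must be non-negative")
  if (lo > hi) stop("invalid truncation range")
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  mean + sd * qnorm(runif(n, plo, phi))
}

# Uniform random rotation matrix (via quaternions); columns map local seed
# axes (long, width, thickness) to world (z, y, x) components.
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Meridional profile of the seed surface: cross-section radius multiplier
# at normalised position t in [-1, 1] along the long axis. pinch = 0 is
# the ellipsoid; larger values slim the shape away from its widest
# cross-section (almond/waisted form) while keeping the poles blunt.
# taper shrinks the cross-section linearly toward the t = +1 (micropylar)
# pole, making the shape asymmetric (teardrop).
.profile_g <- function(t, pinch, taper) {
  sqrt(pmax(0, 1 - t^2)) * (1 - pinch * t^2) * (1 - taper * (1 + t) / 2)
}

# Maximum of the profile over t (the relative position of the widest
# cross-section), computed numerically.
.profile_max <- function(pinch, taper) {
  opt <- optimize(function(t) .profile_g(t, pinch, taper),
                  interval = c(-1, 1), maximum = TRUE)
  opt$objective
}

# Volume of the generating shape relative to (pi/6) * L * W * T equals
# (3/4) * integral(g^2) / M^2; used to solve for the pinch parameter.
.profile_vol_factor <- function(pinch, taper) {
  gg <- function(t) .profile_g(t, pinch, taper)^2
  I <- stats::integrate(gg, -1, 1)$value
  0.75 * I / .profile_max(pinch, taper)^2
}

#' Population parameters of the controllable phantom traits
#'
#' Mean, SD and admissible range for seed length, width, thickness (mm),
#' coat thickness (mm) and fullness (kernel volume / seed volume) of the
#' default phantom population.
#'
#' @return A data.frame with columns `trait`, `mean`, `sd`, `lo`, `hi`.
#' @export
default_population <- function() {
  data.frame(
    trait = c("length", "width", "thickness", "coat_thickness", "fullness"),
    mean = c(9.22, 5.40, 4.86, 0.16, 0.54),
    sd = c(0.70, 0.50, 0.41, 0.02, 0.06),
    lo = c(7.26, 4.44, 3.67, 0.10, 0.30),
    hi = c(11.16, 8.49, 6.91, 0.21, 0.67),
    stringsAsFactors = FALSE)
}

#' Default phantom grayscale model
#'
#' Normalised intensities of the four phases and the additive noise SD.
#' Coat and kernel are both bright (the coat slightly brighter, as palisade
#' tissue is denser than embryo tissue); the cavity is dark but above the
#' background.
#' @return Named list of intensities and `noise_sd`.
#' @export
default_intensities <- function() {
  list(background = 0.08, cavity = 0.22, kernel = 0.72, coat = 0.88,
       noise_sd = 0.04)
}

# Waist parameter calibrated once so that the default population's mean
# generated seed volume matches the target mean volume of 100.34 mm^3 given
# the default taper (see the methods vignette); a config value, not a fit
# to any measurement.
.default_pinch <- 0.643
.default_taper <- 0.12

#' Construct a seed phantom specification
#'
#' @param semi_axes_mm numeric (a, b, c), a >= b >= c, the half-extents of
#'   the generating shape along its long, width and thickness axes.
#' @param coat_thickness_mm coat shell thickness (constant inward normal
#'   distance), must be < c.
#' @param target_fullness desired kernel volume / seed volume, in (0, 1).
#' @param taper in \[0, 1): linear shrink of the cross-section toward the
#'   micropylar pole (teardrop asymmetry).
#' @param pinch meridional waist parameter in \[0, 1) (0 = ellipsoid;
#'   larger values slim the body away from the widest cross-section).
#' @param cavity_pole unit direction (z, y, x components) of the pole where
#'   the cavity cap sits.
#' @param orientation 3x3 rotation matrix mapping local axes to world
#'   (z, y, x); identity by default.
#' @param center_mm seed centre in world mm (z, y, x).
#' @param intensities named list as [default_intensities()].
#' @param noise_sd additive Gaussian noise SD (overrides the intensities
#'   entry if given).
#' @param rng_seed integer seed driving all randomness for this seed.
#' @return A `seed_spec` object.
#' @export
seed_spec <- function(semi_axes_mm, coat_thickness_mm, target_fullness,
                      taper = .default_taper, pinch = .default_pinch,
                      cavity_pole = c(0, 0, 1), orientation = diag(3),
                      center_mm = c(0, 0, 0),
                      intensities = default_intensities(),
                      noise_sd = NULL, rng_seed = 1L) {
  a <- semi_axes_mm[1]; b <- semi_axes_mm[2]; cc <- semi_axes_mm[3]
  if (!(a >= b && b >= cc && cc > 0)) stop("semi-axes must satisfy a >= b >= c > 0")
  if (coat_thickness_mm <= 0 || coat_thickness_mm >= cc)
    stop("coat thickness must be positive and smaller than semi-axis c")
  if (!is.na(target_fullness) &&
      (target_fullness <= 0 || target_fullness >= 1))
    stop("target_fullness must be in (0, 1), or NA for a cavity-free seed")
  if (taper < 0 || taper >= 1) stop("taper must be in [0, 1)")
  ii <- intensities
  if (!is.null(noise_sd)) ii$noise_sd <- noise_sd
  if (!(ii$background < ii$cavity && ii$cavity < ii$kernel &&
        ii$cavity < ii$coat))
    stop("intensities must satisfy background < cavity < {kernel, coat}")
  if (ii$noise_sd < 0) stop("noise_sd must be non-negative")
  cp <- cavity_pole / sqrt(sum(cavity_pole^2))
  structure(list(semi_axes_mm = c(a, b, cc),
                 coat_thickness_mm = coat_thickness_mm,
                 target_fullness = target_fullness,
                 taper = taper, pinch = pinch,
                 cavity_pole = cp, orientation = orientation,
                 center_mm = center_mm, intensities = ii,
                 noise_sd = ii$noise_sd, rng_seed = as.integer(rng_seed)),
            class = "seed_spec")
}

#' Draw phantom specifications from a trait population
#'
#' Seed length is drawn from its truncated normal; width and thickness are
#' drawn jointly (correlation `cor_wt`, as in real seed populations, where
#' the two dimensions co-vary strongly) truncated to their ranges and to the
#' ordering L >= W >= T required of the generating shape; coat thickness and
#' fullness are drawn independently from their truncated normals.
#'
#' @param population data.frame as [default_population()].
#' @param n number of seeds.
#' @param rng_seed integer root seed; the i-th spec gets `rng_seed + i` as
#'   its own seed.
#' @param cor_wt correlation between width and thickness draws.
#' @param taper,pinch shape parameters passed to every spec.
#' @param intensities grayscale model, see [default_intensities()].
#' @param random_orientation logical; draw a uniform random orientation and
#'   cavity pole per seed (default) or keep axis-aligned.
#' @return List of `seed_spec` objects of length `n`.
#' @export
sample_specs <- function(population = default_population(), n,
                         rng_seed = 1L, cor_wt = 0.8,
                         taper = .default_taper,
                         pinch = .default_pinch,
                         intensities = default_intensities(),
                         random_orientation = TRUE) {
  if (n < 1) stop("n must be >= 1")
  if (any(population$sd < 0)) stop("SD must be non-negative")
  if (any(population$mean <= 0)) stop("means must be positive")
  p <- population
  rownames(p) <- p$trait
  M <- .profile_max(pinch, taper)
  .with_seed(rng_seed, {
    specs <- vector("list", n)
    for (i in seq_len(n)) {
      L <- .truncnorm(1, p["length", "mean"], p["length", "sd"],
                      p["length", "lo"], p["length", "hi"])
      ok <- FALSE
      for (try in 1:1000) {
        z1 <- rnorm(1); z2 <- rnorm(1)
        W <- p["width", "mean"] + p["width", "sd"] * z1
        Tt <- p["thickness", "mean"] + p["thickness", "sd"] *
          (cor_wt * z1 + sqrt(1 - cor_wt^2) * z2)
        if (W >= p["width", "lo"] && W <= p["width", "hi"] &&
            Tt >= p["thickness", "lo"] && Tt <= p["thickness", "hi"] &&
            L >= W && W >= Tt) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw ordered dimensions; check population")
      ct <- .truncnorm(1, p["coat_thickness", "mean"],
                       p["coat_thickness", "sd"],
                       p["coat_thickness", "lo"], p["coat_thickness", "hi"])
      fu <- .truncnorm(1, p["fullness", "mean"], p["fullness", "sd"],
                       p["fullness", "lo"], p["fullness", "hi"])
      rot <- if (random_orientation) .random_rotation() else diag(3)
      pole <- if (random_orientation) {
        u <- rnorm(3); u / sqrt(sum(u^2))
      } else c(0, 0, 1)
      specs[[i]] <- seed_spec(
        semi_axes_mm = c(L / 2, W / (2 * M), Tt / (2 * M)),
        coat_thickness_mm = ct, target_fullness = fu,
        taper = taper, pinch = pinch,
        cavity_pole = pole, orientation = rot,
        intensities = intensities, rng_seed = rng_seed + i)
    }
    specs
  })
}

# Additive decomposition of an array over axis contributions:
# out[z,y,x] = az[z] + ay[y] + ax[x], as a flat vector.
.axis_sum <- function(az, ay, ax) {
  nz <- length(az); ny <- length(ay); nx <- length(ax)
  rep(az, times = ny * nx) +
    rep(rep(ay, each = nz), times = nx) +
    rep(ax, each = nz * ny)
}

# Rasterise the generating shape of a spec on a voxel grid: the signed
# first-order normal distance to the outer surface (positive inside) and
# the fractional occupancy derived from it by a one-voxel linear
# partial-volume ramp.
.render_outer <- function(spec, spacing_mm, margin_mm = 0.2) {
  ax <- spec$semi_axes_mm
  R <- spec$orientation
  half <- sqrt((R^2) %*% (ax^2))[, 1] + margin_mm
  dims <- 2L * as.integer(ceiling(half / spacing_mm)) + 1L
  ctr <- (dims - 1) / 2 * spacing_mm
  gz <- (seq_len(dims[1]) - 1) * spacing_mm - ctr[1]
  gy <- (seq_len(dims[2]) - 1) * spacing_mm - ctr[2]
  gx <- (seq_len(dims[3]) - 1) * spacing_mm - ctr[3]
  dn <- cpp_spindle_dist(gz, gy, gx, R, ax[1], ax[2], ax[3],
                         spec$pinch, spec$taper)
  O <- pmin(1, pmax(0, 0.5 + dn / spacing_mm))
  list(O = array(O, dim = dims), dn = dn, dims = dims, ctr = ctr,
       gz = gz, gy = gy, gx = gx, spacing_mm = spacing_mm)
}

# Full phantom rendering: outer shape, constant-thickness coat (inner
# surface at normal depth coat_thickness_mm), polar cavity cap calibrated
# to the target fullness, component masks, fractional fields, and the
# noise-free intensity contribution.
.render_seed <- function(spec, spacing_mm, margin_mm = 0.2) {
  ctv <- spec$coat_thickness_mm / spacing_mm
  if (ctv < 2) stop("under-resolved: coat spans fewer than 2 voxels")
  geo <- .render_outer(spec, spacing_mm, margin_mm)
  dims <- geo$dims
  ct <- spec$coat_thickness_mm
  inner_vec <- geo$dn >= ct
  n_inner <- sum(inner_vec)
  n_seed <- sum(geo$dn >= 0)
  if (n_seed == 0) stop("under-resolved: empty seed")
  if (n_inner == 0) stop("fullness unreachable: coat fills the whole seed")

  # cavity cap centre: the innermost-surface point along the cavity pole
  pole <- spec$cavity_pole
  iv <- which(inner_vec)
  i0 <- iv - 1L
  zc <- geo$gz[(i0 %% dims[1]) + 1L]
  yc <- geo$gy[((i0 %/% dims[1]) %% dims[2]) + 1L]
  xc <- geo$gx[(i0 %/% (dims[1] * dims[2])) + 1L]
  ip <- which.max(zc * pole[1] + yc * pole[2] + xc * pole[3])
  ppt <- c(zc[ip], yc[ip], xc[ip])
  dist2 <- cpp_dist2_point(geo$gz, geo$gy, geo$gx, ppt)

  f_max <- n_inner / n_seed
  target <- spec$target_fullness
  if (is.na(target)) target <- f_max  # cavity-free seed
  if (target > f_max + 1e-9)
    stop(sprintf(
      "fullness unreachable: target %.3f exceeds achievable maximum %.3f",
      target, f_max))
  Rcap <- 0
  if (f_max - target > 0.0049) {
    hi <- sqrt(max(dist2[iv])) + spacing_mm
    Rcap <- cpp_fullness_bisect(dist2, inner_vec, n_seed,
                                target, 0, hi, 0.004, 50L)
  }
  ii <- spec$intensities
  ph <- cpp_render_phases(geo$dn, dist2, spacing_mm, ct, Rcap,
                          ii$coat, ii$kernel, ii$cavity)
  to_arr <- function(v) { dim(v) <- dims; v }
  list(O = geo$O, dn = geo$dn, dist2 = dist2,
       contrib = to_arr(ph$contrib),
       seed_bin = to_arr(ph$seed), kernel_bin = to_arr(ph$kernel),
       coat_bin = to_arr(ph$coat), cavity_bin = to_arr(ph$cavity),
       cavity_radius_mm = Rcap,
       realized_fullness = ph$counts[2] / ph$counts[1],
       counts = ph$counts,
       dims = dims, spacing_mm = spacing_mm, geo = geo)
}

# Fractional kernel occupancy field (for ground-truth kernel meshing).
.kern_frac_field <- function(r, spec) {
  sp <- r$spacing_mm
  occ_in <- pmin(1, pmax(0, 0.5 + (r$dn - spec$coat_thickness_mm) / sp))
  cap <- if (r$cavity_radius_mm > 0)
    pmin(1, pmax(0, 0.5 + (r$cavity_radius_mm - sqrt(r$dist2)) / sp))
  else 0
  kf <- occ_in * (1 - cap)
  dim(kf) <- r$dims
  kf
}

#' Calibrate the cavity-cap radius for a target fullness
#'
#' Bisects the radius of the polar spherical cap until the voxel-counted
#' kernel/seed volume ratio is within 0.005 of the spec's target fullness.
#'
#' @param spec a `seed_spec`.
#' @param spacing_mm rasterisation pitch, mm.
#' @return List with `cavity_radius_mm`, `realized_fullness` and the
#'   achievable `max_fullness`.
#' @export
calibrate_cavity <- function(spec, spacing_mm = 0.04) {
  r <- .render_seed(spec, spacing_mm)
  list(cavity_radius_mm = r$cavity_radius_mm,
       realized_fullness = r$realized_fullness,
       max_fullness = sum(r$kernel_bin | r$cavity_bin) / sum(r$seed_bin))
}

# Analytic ground-truth length/width/thickness of the generating shape.
.spec_lwt <- function(spec) {
  M <- .profile_max(spec$pinch, spec$taper)
  c(length = 2 * spec$semi_axes_mm[1],
    width = 2 * spec$semi_axes_mm[2] * M,
    thickness = 2 * spec$semi_axes_mm[3] * M)
}

# Ground-truth trait row from a rendered phantom. Surface areas require
# two isosurface extractions; `areas = FALSE` skips them (NA) for
# population runs that do not consume them.
.ground_truth_row <- function(r, spec, label = 1L, areas = TRUE) {
  sp <- r$spacing_mm
  vx <- sp^3
  lwt <- .spec_lwt(spec)
  seed_area <- kern_area <- NA_real_
  if (areas) {
    seed_area <- mesh_from_field(r$O, sp)$area_mm2
    kern_area <- mesh_from_field(.kern_frac_field(r, spec), sp)$area_mm2
  }
  data.frame(
    seed_id = label,
    seed_length_mm = lwt[["length"]],
    seed_width_mm = lwt[["width"]],
    seed_thickness_mm = lwt[["thickness"]],
    seed_volume_mm3 = sum(r$seed_bin) * vx,
    seed_surface_area_mm2 = seed_area,
    kernel_volume_mm3 = sum(r$kernel_bin) * vx,
    kernel_surface_area_mm2 = kern_area,
    cavity_volume_mm3 = sum(r$cavity_bin) * vx,
    coat_volume_mm3 = sum(r$coat_bin) * vx,
    avg_coat_thickness_mm = spec$coat_thickness_mm,
    seed_fullness = r$realized_fullness,
    cavity_radius_mm = r$cavity_radius_mm)
}

#' Generate a single seed phantom
#'
#' Renders the spec on its own voxel grid: tapered-spindle outer surface,
#' coat shell of constant inward thickness, spherical-cap cavity between
#' kernel and coat at the cavity pole (radius calibrated to the target
#' fullness), kernel as the remainder. The grayscale volume has
#' partial-volume (fractional occupancy) edges and additive Gaussian noise.
#'
#' @param spec a `seed_spec`.
#' @param spacing_mm voxel pitch in mm (default 0.04; the coat must span at
#'   least 2 voxels).
#' @param margin_mm background margin around the seed.
#' @param gt_areas compute ground-truth surface areas (two isosurface
#'   extractions); disable for large population runs that do not use them.
#' @return List with `volume` ([ct_volume]), `masks` (named list of
#'   [ct_mask]: seed, kernel, coat, cavity), `ground_truth` (one-row
#'   data.frame of realized trait values) and `spec`.
#' @export
make_seed <- function(spec, spacing_mm = 0.04, margin_mm = 0.2,
                      gt_areas = TRUE) {
  r <- .render_seed(spec, spacing_mm, margin_mm)
  ii <- spec$intensities
  img <- ii$background * (1 - as.vector(r$O)) + as.vector(r$contrib)
  if (spec$noise_sd > 0) {
    img <- .with_seed(spec$rng_seed,
                      img + rnorm(length(img), 0, spec$noise_sd))
  }
  img <- pmin(1, pmax(0, img))
  vol <- ct_volume(array(img, dim = r$dims), spacing_mm, "phantom")
  masks <- list(seed = ct_mask(r$seed_bin, spacing_mm),
                kernel = ct_mask(r$kernel_bin, spacing_mm),
                coat = ct_mask(r$coat_bin, spacing_mm),
                cavity = ct_mask(r$cavity_bin, spacing_mm))
  list(volume = vol, masks = masks,
       ground_truth = .ground_truth_row(r, spec, areas = gt_areas),
       spec = spec)
}

#' Generate a multi-seed scan scene
#'
#' Places the seeds (bounding-sphere packing with rejection sampling) in a
#' textured low-intensity foam-like background slab and renders them with
#' instance labels 1..n and per-seed ground truth.
#'
#' @param specs list of `seed_spec`.
#' @param spacing_mm voxel pitch, mm.
#' @param min_gap_mm minimum gap between seed bounding spheres (0 allows
#'   touching).
#' @param rng_seed seed for placement, foam texture and noise.
#' @param scene_size_mm optional (z, y, x) scene extent in mm; auto-sized
#'   when NULL.
#' @param max_attempts rejection-sampling attempts per seed before failing.
#' @return List with `volume` ([ct_volume]), `labels` (integer array,
#'   background 0) and `ground_truth` (data.frame, one row per seed).
#' @export
make_scene <- function(specs, spacing_mm = 0.06, min_gap_mm = 0.5,
                       rng_seed = 1L, scene_size_mm = NULL,
                       max_attempts = 1000L) {
  if (min_gap_mm < 0) stop("min_gap_mm must be >= 0")
  n <- length(specs)
  rads <- vapply(specs, function(s) s$semi_axes_mm[1], numeric(1))
  marg <- 0.35
  auto <- is.null(scene_size_mm)
  ncol_grid <- min(n, max(1L, ceiling(sqrt(n))))
  if (n <= 4) ncol_grid <- n
  nrow_grid <- ceiling(n / ncol_grid)
  cell <- 2 * max(rads) + min_gap_mm + 0.2
  if (auto) {
    scene_size_mm <- c(2 * max(rads) + 2 * marg,
                       nrow_grid * cell + 2 * marg,
                       ncol_grid * cell + 2 * marg)
  }
  centers <- matrix(0, n, 3)
  .with_seed(rng_seed, {
    for (i in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        if (auto) {
          # jittered grid placement: guaranteed feasible for auto-sized scenes
          gy <- (i - 1) %/% ncol_grid
          gx <- (i - 1) %% ncol_grid
          jit <- runif(3, -0.04, 0.04) * cell
          cand <- c(scene_size_mm[1] / 2 + jit[1],
                    marg + (gy + 0.5) * cell + jit[2],
                    marg + (gx + 0.5) * cell + jit[3])
        } else {
          cand <- vapply(1:3, function(k) {
            lo <- rads[i] + marg
            hi <- scene_size_mm[k] - rads[i] - marg
            if (hi <= lo) (lo + hi) / 2 else runif(1, lo, hi)
          }, numeric(1))
        }
        ok <- TRUE
        if (i > 1) {
          for (j in seq_len(i - 1)) {
            if (sqrt(sum((cand - centers[j, ])^2)) <
                rads[i] + rads[j] + min_gap_mm) { ok <- FALSE; break }
          }
        }
        if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) stop("packing failed")
    }
  })

  dims <- as.integer(ceiling(scene_size_mm / spacing_mm))
  ii <- specs[[1]]$intensities
  img <- array(ii$background, dim = dims)
  labels <- array(0L, dim = dims)
  gt <- NULL
  for (i in seq_len(n)) {
    r <- .render_seed(specs[[i]], spacing_mm)
    lo <- as.integer(round(centers[i, ] / spacing_mm - (r$dims - 1) / 2)) + 1L
    hi <- lo + r$dims - 1L
    src_lo <- pmax(1L, 2L - lo)
    lo <- pmax(lo, 1L)
    hi2 <- pmin(hi, dims)
    src_hi <- src_lo + (hi2 - lo)
    zi <- lo[1]:hi2[1]; yi <- lo[2]:hi2[2]; xi <- lo[3]:hi2[3]
    zs <- src_lo[1]:src_hi[1]; ys <- src_lo[2]:src_hi[2]
    xs <- src_lo[3]:src_hi[3]
    Opart <- r$O[zs, ys, xs, drop = FALSE]
    img[zi, yi, xi] <- img[zi, yi, xi] * (1 - Opart) +
      r$contrib[zs, ys, xs, drop = FALSE]
    lpart <- labels[zi, yi, xi]
    lpart[r$seed_bin[zs, ys, xs, drop = FALSE]] <- i
    labels[zi, yi, xi] <- lpart
    row <- .ground_truth_row(r, specs[[i]], label = i)
    gt <- rbind(gt, row)
  }
  img <- .with_seed(rng_seed + 1L, {
    # foam-like texture: smoothed coarse noise, plus voxel noise
    coarse <- array(rnorm(prod(pmax(dims %/% 8L, 1L))),
                    dim = pmax(dims %/% 8L, 1L))
    tex <- coarse[pmin(dim(coarse)[1], (seq_len(dims[1]) - 1L) %/% 8L + 1L),
                  pmin(dim(coarse)[2], (seq_len(dims[2]) - 1L) %/% 8L + 1L),
                  pmin(dim(coarse)[3], (seq_len(dims[3]) - 1L) %/% 8L + 1L),
                  drop = FALSE]
    tex <- array(cpp_box_blur(c_vec(tex), dims, 4L), dim = dims)
    tex <- tex / max(sd(tex), 1e-9) * 0.015
    img + tex * (labels == 0L) + rnorm(length(img), 0, ii$noise_sd)
  })
  img <- array(pmin(1, pmax(0, img)), dim = dims)
  list(volume = ct_volume(img, spacing_mm, "phantom scene"),
       labels = labels, ground_truth = gt)
}

#' The canonical three-seed scan scene
#'
#' Three mean-parameter seeds in distinct orientations on the foam slab,
#' mirroring the acquisition layout of three seeds per scan.
#'
#' @param rng_seed integer seed.
#' @param spacing_mm voxel pitch, mm.
#' @return As [make_scene()].
#' @export
canonical_scene <- function(rng_seed = 1L, spacing_mm = 0.07) {
  pop <- default_population()
  pop$sd <- rep(0, nrow(pop))
  specs <- sample_specs(pop, 3, rng_seed = rng_seed)
  make_scene(specs, spacing_mm = spacing_mm, min_gap_mm = 0.5,
             rng_seed = rng_seed + 100L)
}

#' Write phantom ground truth to CSV
#'
#' @param gt ground-truth data.frame from [make_seed()]/[make_scene()].
#' @param path output CSV path.
#' @export
write_ground_truth <- function(gt, path) {
  write.csv(gt, path, row.names = FALSE)
  invisible(path)
}
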