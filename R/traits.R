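# Surface modelling and morphological trait extraction.

#' Isosurface mesh of a scalar field
#'
#' Extracts the 0.5 level surface of a fractional-occupancy field by
#' marching tetrahedra and scales vertex coordinates to mm. The field is
#' padded with a zero layer so surfaces close at the array border. By
#' default the field is first smoothed with a one-voxel box filter: an
#' occupancy ramp only one voxel wide kinks the piecewise-linear
#' interpolant and crumples the extracted surface (about +5% area on
#' spheres); widening the ramp removes the artefact while leaving the
#' level-set position unchanged. Fields whose smoothed maximum never
#' reaches the level (e.g. a single-voxel mask) are meshed unsmoothed.
#'
#' @param field 3D numeric array (fractional occupancy in \[0, 1\]).
#' @param spacing_mm voxel pitch, mm.
#' @param level iso level (default 0.5).
#' @param check_watertight verify that every mesh edge borders exactly two
#'   faces (skippable for speed).
#' @param presmooth widen the occupancy ramp with a one-voxel box filter
#'   before extraction (see above).
#' @return A `seed_mesh`: `vertices` (n x 3, columns z/y/x in mm), `faces`
#'   (m x 3 vertex indices), `watertight`, `area_mm2`, `volume_mm3`.
#' @export
mesh_from_field <- function(field, spacing_mm, level = 0.5,
                            check_watertight = TRUE, presmooth = TRUE) {
  d <- dim(field)
  pad <- array(0, dim = d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- field
  if (presmooth) {
    sm <- cpp_box_blur(c_vec(pad), .dims(pad), 1L)
    if (max(sm) > level) {
      pad <- sm
      dim(pad) <- d + 2L
    }
  }
  res <- cpp_march_tets(c_vec(pad), .dims(pad), level)
  V <- res$vertices
  if (nrow(V) == 0L) stop("empty mask")
  V <- (V - 1) * spacing_mm  # remove padding offset, scale to mm
  av <- cpp_mesh_area_volume(V, res$faces)
  structure(list(vertices = V, faces = res$faces,
                 watertight = if (check_watertight)
                   cpp_mesh_watertight(res$faces, nrow(V)) else NA,
                 area_mm2 = av[1], volume_mm3 = av[2],
                 spacing_mm = spacing_mm),
            class = "seed_mesh")
}

#' @export
print.seed_mesh <- function(x, ...) {
  cat(sprintf(
    "<seed_mesh> %d vertices, %d faces, area %.3f mm^2, volume %.3f mm^3%s\n",
    nrow(x$vertices), nrow(x$faces), x$area_mm2, x$volume_mm3,
    if (x$watertight) ", watertight" else ""))
  invisible(x)
}

#' Isosurface mesh of a binary mask
#'
#' For sub-voxel surface placement the binary mask is smoothed by the
#' meshing step's box filter before extracting the 0.5 isosurface (the
#' smoothed mask is a partial-volume estimate of the underlying surface).
#' When a fractional occupancy field is available, pass it as
#' `smooth_field` and it is used instead. Degenerate masks whose smoothed
#' field never reaches the level (e.g. a single voxel) fall back to the
#' raw binary field.
#'
#' @param m a [ct_mask].
#' @param smooth_field optional [ct_volume] or array of fractional
#'   occupancy aligned with `m`.
#' @param check_watertight verify that every mesh edge borders exactly two
#'   faces (skippable for speed).
#' @return A `seed_mesh` (see [mesh_from_field()]).
#' @export
mesh_from_mask <- function(m, smooth_field = NULL,
                           check_watertight = TRUE) {
  stopifnot(inherits(m, "ct_mask"))
  if (!any(m$data)) stop("empty mask")
  if (!is.null(smooth_field)) {
    f <- if (inherits(smooth_field, "ct_volume")) smooth_field$data
         else smooth_field
    return(mesh_from_field(f, m$spacing_mm,
                           check_watertight = check_watertight))
  }
  f <- m$data
  storage.mode(f) <- "double"
  mesh_from_field(f, m$spacing_mm, check_watertight = check_watertight)
}

# Quasi-uniform unit directions (Fibonacci sphere).
.fib_dirs <- function(k) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(phi), sin(phi) * cos(theta), sin(phi) * sin(theta))
}

# Farthest-pair (diameter) of a point set: extreme points along quasi-
# uniform directions seed an alternating farthest-point refinement.
.diameter_pair <- function(V) {
  D <- .fib_dirs(128L)
  proj <- V %*% t(D)
  cand <- unique(c(vapply(seq_len(ncol(proj)),
                          function(k) which.max(proj[, k]), integer(1)),
                   vapply(seq_len(ncol(proj)),
                          function(k) which.min(proj[, k]), integer(1))))
  C <- V[cand, , drop = FALSE]
  dm <- as.matrix(stats::dist(C))
  ij <- arrayInd(which.max(dm), dim(dm))
  p <- cand[ij[1]]; q <- cand[ij[2]]
  best <- dm[ij]
  for (it in 1:30) {
    dp <- sqrt(colSums((t(V) - V[p, ])^2))
    q2 <- which.max(dp)
    dq <- sqrt(colSums((t(V) - V[q2, ])^2))
    p2 <- which.max(dq)
    d2 <- dq[p2]
    if (d2 <= best + 1e-12) break
    best <- d2; p <- p2; q <- q2
  }
  list(i = p, j = q, length = best)
}

#' Feret dimensions (length, width, thickness) of a mesh
#'
#' Length is the maximum pairwise vertex distance; width is the maximum
#' caliper extent among directions orthogonal to the length axis (the
#' planar diameter of the projected vertex set, found on its convex hull);
#' thickness is the extent along the axis orthogonal to both.
#'
#' @param mesh a `seed_mesh`.
#' @return Named numeric: `length`, `width`, `thickness` (mm), with
#'   length >= width >= thickness.
#' @export
feret_dims <- function(mesh) {
  V <- mesh$vertices
  if (nrow(V) < 4L) stop("degenerate geometry: fewer than 4 vertices")
  dp <- .diameter_pair(V)
  u <- V[dp$j, ] - V[dp$i, ]
  len <- dp$length
  if (len <= 0) stop("degenerate geometry: zero extent")
  u <- u / len
  # orthonormal basis of the plane orthogonal to u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  P <- cbind(V %*% e1, V %*% e2)
  hull <- chull(P)
  H <- P[hull, , drop = FALSE]
  dm <- as.matrix(stats::dist(H))
  ij <- arrayInd(which.max(dm), dim(dm))
  wid <- dm[ij]
  wdir2 <- H[ij[2], ] - H[ij[1], ]
  wdir2 <- wdir2 / sqrt(sum(wdir2^2))
  wdir <- wdir2[1] * e1 + wdir2[2] * e2
  tdir <- c(u[2] * wdir[3] - u[3] * wdir[2],
            u[3] * wdir[1] - u[1] * wdir[3],
            u[1] * wdir[2] - u[2] * wdir[1])
  tdir <- tdir / sqrt(sum(tdir^2))
  tproj <- V %*% tdir
  thk <- max(tproj) - min(tproj)
  out <- c(length = len, width = wid, thickness = thk)
  if (out["width"] > out["length"]) out[c(1, 2)] <- out[c(2, 1)]
  if (out["thickness"] > out["width"])
    out[c(2, 3)] <- sort(out[c(2, 3)], decreasing = TRUE)
  out
}

#' Average coat thickness by maximal inscribed spheres
#'
#' Local thickness in the sense of shell structures: every coat voxel is
#' assigned the diameter of the largest sphere that fits in the coat and
#' covers it, and the assigned values are averaged. Sphere radii are
#' distance-transform values corrected for the half-voxel offset between
#' voxel centres and the digitised boundary; the loss from sampling
#' sphere centres only at voxel centres is compensated by an additive
#' correction of 0.42 voxel, calibrated once against constant-thickness
#' analytic shells (flat slabs, spherical and seed-shaped shells spanning
#' the 2-6 voxel thickness range).
#'
#' @param coat a [ct_mask] of the coat shell.
#' @param spacing_mm voxel pitch in mm (defaults to the mask's).
#' @param regularize apply a 3-voxel majority filter to the mask first
#'   (recommended for masks from noisy segmentations; ground-truth masks
#'   are measured as-is).
#' @return Mean local thickness in mm.
#' @export
avg_coat_thickness <- function(coat, spacing_mm = NULL,
                               regularize = FALSE) {
  stopifnot(inherits(coat, "ct_mask"))
  if (!any(coat$data)) stop("empty mask")
  if (is.null(spacing_mm)) spacing_mm <- coat$spacing_mm
  d <- .dims(coat$data)
  msk <- coat$data
  if (regularize) {
    # majority filter: suppresses single-voxel boundary roughness from
    # noisy segmentation, which would otherwise inflate the maximal
    # inscribed spheres; thickness-neutral for smooth shells
    sm <- array(cpp_box_blur(as.numeric(msk), d, 1L), dim = d) >= 0.5
    if (any(sm)) msk <- sm
  }
  th <- cpp_local_thickness(c_vec(msk), d, 0.7)
  (mean(th[as.vector(msk)]) + 0.42) * spacing_mm
}

#' Cross-check coat thickness estimator from volume and areas
#'
#' For a thin shell, thickness is approximately 2 V / (A_outer + A_inner).
#'
#' @param coat_volume_mm3 coat volume.
#' @param outer_area_mm2 outer (seed) surface area.
#' @param inner_area_mm2 inner shell surface area.
#' @return Thickness estimate in mm.
#' @export
coat_thickness_from_areas <- function(coat_volume_mm3, outer_area_mm2,
                                      inner_area_mm2) {
  if (outer_area_mm2 + inner_area_mm2 <= 0) stop("zero denominator")
  2 * coat_volume_mm3 / (outer_area_mm2 + inner_area_mm2)
}

#' Compute the 11 morphological traits of a segmented seed
#'
#' Volumes are voxel counts times the voxel volume; seed and kernel surface
#' areas and the seed's Feret dimensions come from isosurface meshes;
#' average coat thickness uses the maximal-inscribed-sphere estimator;
#' fullness is kernel volume over seed volume.
#'
#' @param comp a `seed_components` object (see [seed_components()]).
#' @param seed_id identifier stored in the output row.
#' @return One-row data.frame with the 11 traits.
#' @export
compute_traits <- function(comp, seed_id = 1L) {
  stopifnot(inherits(comp, "seed_components"))
  if (length(comp$flags) > 0)
    stop(sprintf("refusing flagged seed: %s",
                 paste(comp$flags, collapse = ", ")))
  sp <- comp$spacing_mm
  vx <- sp^3
  n_seed <- sum(comp$seed_mask$data)
  n_kern <- sum(comp$kernel_mask$data)
  n_coat <- sum(comp$coat_mask$data)
  n_cav <- sum(comp$cavity_mask$data)
  seed_mesh <- mesh_from_mask(comp$seed_mask, check_watertight = FALSE)
  kern_mesh <- mesh_from_mask(comp$kernel_mask, check_watertight = FALSE)
  lwt <- feret_dims(seed_mesh)
  act <- avg_coat_thickness(comp$coat_mask, sp, regularize = TRUE)
  out <- data.frame(
    seed_id = seed_id,
    seed_length_mm = unname(lwt["length"]),
    seed_width_mm = unname(lwt["width"]),
    seed_thickness_mm = unname(lwt["thickness"]),
    seed_volume_mm3 = n_seed * vx,
    seed_surface_area_mm2 = seed_mesh$area_mm2,
    kernel_volume_mm3 = n_kern * vx,
    kernel_surface_area_mm2 = kern_mesh$area_mm2,
    cavity_volume_mm3 = n_cav * vx,
    coat_volume_mm3 = n_coat * vx,
    avg_coat_thickness_mm = act,
    seed_fullness = n_kern / n_seed)
  stopifnot(isTRUE(all.equal(out$seed_volume_mm3,
                             out$kernel_volume_mm3 + out$coat_volume_mm3 +
                               out$cavity_volume_mm3)))
  out
}

#' Derived evaluation indices of seed morphological structure
#'
#' Three ratios summarising coat and internal structure:
#' coat specific surface area = seed (coat) surface area / coat volume
#' (per mm); coat thickness ratio = average coat thickness / seed
#' thickness; seed density ratio = cavity volume / kernel volume (smaller
#' means a denser seed).
#'
#' @param traits data.frame with the 11 trait columns (any extra columns
#'   are carried through).
#' @return `traits` with three new columns: `coat_specific_surface_area`,
#'   `coat_thickness_ratio`, `seed_density_ratio`.
#' @export
compute_indices <- function(traits) {
  req <- c("seed_surface_area_mm2", "coat_volume_mm3",
           "avg_coat_thickness_mm", "seed_thickness_mm",
           "cavity_volume_mm3", "kernel_volume_mm3")
  miss <- setdiff(req, names(traits))
  if (length(miss) > 0)
    stop("missing trait columns: ", paste(miss, collapse = ", "))
  if (any(traits$coat_volume_mm3 <= 0) || any(traits$seed_thickness_mm <= 0) ||
      any(traits$kernel_volume_mm3 <= 0))
    stop("zero denominator")
  traits$coat_specific_surface_area <-
    traits$seed_surface_area_mm2 / traits$coat_volume_mm3
  traits$coat_thickness_ratio <-
    traits$avg_coat_thickness_mm / traits$seed_thickness_mm
  traits$seed_density_ratio <-
    traits$cavity_volume_mm3 / traits$kernel_volume_mm3
  traits
}
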