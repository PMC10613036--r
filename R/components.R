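# Per-seed component segmentation: kernel, coat and cavity from the
# extracted seed sub-volume, by per-seed gray-level histogram analysis
# combined with the geometry of the shell.

#' Seed component masks
#'
#' Container for the kernel / coat / cavity partition of one seed. The
#' partition invariants (pairwise disjoint, union equal to the seed mask)
#' are asserted at construction.
#'
#' @param seed_mask,kernel_mask,coat_mask,cavity_mask [ct_mask]s on the
#'   same per-seed grid.
#' @param flags character vector of quality flags (see [flag_damage()]).
#' @return A `seed_components` object.
#' @export
seed_components <- function(seed_mask, kernel_mask, coat_mask, cavity_mask,
                            flags = character()) {
  for (m in list(seed_mask, kernel_mask, coat_mask, cavity_mask))
    stopifnot(inherits(m, "ct_mask"))
  d <- dim(seed_mask$data)
  stopifnot(identical(d, dim(kernel_mask$data)),
            identical(d, dim(coat_mask$data)),
            identical(d, dim(cavity_mask$data)))
  k <- kernel_mask$data; ct <- coat_mask$data; cv <- cavity_mask$data
  if (any(k & ct) || any(k & cv) || any(ct & cv))
    stop("component masks overlap")
  if (!identical(seed_mask$data, k | ct | cv))
    stop("components do not partition the seed mask")
  structure(list(seed_mask = seed_mask, kernel_mask = kernel_mask,
                 coat_mask = coat_mask, cavity_mask = cavity_mask,
                 spacing_mm = seed_mask$spacing_mm, flags = flags),
            class = "seed_components")
}

#' @export
print.seed_components <- function(x, ...) {
  cat(sprintf(
    "<seed_components> seed %d vox: kernel %d, coat %d, cavity %d%s\n",
    sum(x$seed_mask$data), sum(x$kernel_mask$data), sum(x$coat_mask$data),
    sum(x$cavity_mask$data),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

# Face-connected erosion/dilation, radius 1.
.erode1 <- function(mask, d) {
  out <- cpp_erode6(c_vec(mask), d)
  dim(out) <- d
  out
}
.dilate1 <- function(mask, d) {
  out <- cpp_dilate6(c_vec(mask), d)
  dim(out) <- d
  out
}

#' Segment the kernel of one seed
#'
#' Per-seed gray-level histogram analysis driven by tissue plateau
#' levels. Raw-intensity plateau medians are estimated from
#' depth-resolved regions of the seed: the coat just inside the surface,
#' the kernel as the bright phase of the deep interior, and (when
#' present) the cavity as a dark deep phase. Class boundaries are the
#' midpoints of adjacent plateau levels — which centres each boundary in
#' its partial-volume ramp regardless of class mass imbalance or of
#' smoothing artefacts on thin coats — and the kernel is the largest
#' connected component of its class that stays clear of the 2-voxel
#' seed boundary shell after a radius-1 opening; the one-voxel boundary
#' layer is then re-decided on raw intensities. A winning candidate must
#' show genuine raw-intensity contrast with the remaining shell (guards
#' against splitting pure noise). If no kernel/coat contrast exists, the
#' kernel must be isolated geometrically by the cavity gap: the largest
#' bright component not touching the boundary shell. Holes are filled;
#' failure to find an interior component of meaningful size raises
#' "kernel not found".
#'
#' @param seed_vol [ct_volume] of the extracted seed (background zeroed).
#' @param seed_mask [ct_mask] of the whole seed.
#' @param min_frac minimum kernel size as a fraction of the seed volume.
#' @param smooth_vox pre-smoothing box radius in voxels.
#' @param min_contrast_sd minimum raw-intensity contrast (in units of the
#'   estimated noise SD) between the candidate kernel and the remaining
#'   shell for an intensity-based split to be trusted.
#' @return [ct_mask] of the kernel.
#' @export
segment_kernel <- function(seed_vol, seed_mask, min_frac = 0.05,
                           smooth_vox = 1L, min_contrast_sd = 2.5,
                           .blurred = NULL, .dmask = NULL) {
  stopifnot(inherits(seed_vol, "ct_volume"), inherits(seed_mask, "ct_mask"))
  msk <- seed_mask$data
  if (!any(msk)) stop("seed mask is empty")
  d <- .dims(msk)
  I0 <- seed_vol$data
  I <- if (is.null(.blurred))
    array(cpp_box_blur(c_vec(I0), d, as.integer(smooth_vox)), dim = d)
  else .blurred
  inside_bl <- I[msk]
  inside_raw <- I0[msk]
  rng <- range(inside_bl)
  if (diff(rng) < 1e-9) stop("kernel not found")
  dmask <- if (is.null(.dmask)) array(cpp_edt(c_vec(msk), d), dim = d)
           else .dmask
  shell_border <- msk & dmask <= 2
  min_size <- max(27, round(min_frac * sum(msk)))
  # medians on a deterministic thinning of large vectors (the plateau
  # estimate needs no more than a few hundred thousand values)
  med <- function(v) {
    if (length(v) > 3e5) v <- v[seq.int(1L, length(v), length.out = 3e5)]
    median(v)
  }

  pick_interior <- function(cand) {
    lab <- array(cpp_label(c_vec(cand), d, 6L), dim = d)
    ns <- max(lab)
    if (ns == 0) return(NULL)
    sizes <- tabulate(lab, nbins = ns)
    touching <- unique(lab[lab > 0 & shell_border])
    ok <- setdiff(which(sizes >= min_size), touching)
    if (length(ok) == 0) return(NULL)
    lab == ok[which.max(sizes[ok])]
  }
  interior_of <- function(cls) {
    core <- .erode1(cls & !shell_border, d)
    k <- pick_interior(core)
    if (is.null(k)) return(NULL)
    .dilate1(k, d) & (cls | k) & !shell_border
  }

  # plateau levels from depth-resolved raw intensities: the coat plateau
  # sits just inside the surface (usable even for coats a few voxels
  # thick, whose smoothed values never reach the plateau); the deep
  # interior's bright phase is kernel tissue; a dark deep phase, when
  # present, is the cavity
  cut1 <- .otsu_cut(inside_bl, rng[1], rng[2] + 1e-12)
  bright_sel <- inside_bl >= cut1
  dm_in <- dmask[msk]
  band <- dm_in > 1.2 & dm_in <= 2.6
  deep <- dm_in > max(dm_in) / 2
  p_coat <- if (sum(band) >= 100) med(inside_raw[band]) else NA_real_
  p_kern <- if (sum(deep & bright_sel) >= 100)
    med(inside_raw[deep & bright_sel])
  else if (sum(deep) >= 100) med(inside_raw[deep]) else NA_real_
  # noise estimated on a plateau region: residuals over the whole mask
  # are inflated by partial-volume edges, especially for small seeds
  noise_sel <- if (sum(deep & bright_sel) >= 100) deep & bright_sel
               else rep(TRUE, length(inside_bl))
  noise_est <- stats::mad((inside_raw - inside_bl)[noise_sel])
  cut_lo <- -Inf
  if (!is.na(p_kern)) {
    lowdeep <- deep & inside_bl < p_kern - min_contrast_sd * noise_est
    if (sum(lowdeep) >= 100) {
      p_cav <- med(inside_raw[lowdeep])
      if (p_kern - p_cav >= min_contrast_sd * noise_est)
        cut_lo <- (p_cav + p_kern) / 2
    }
  }
  kern <- NULL
  kern_cuts <- NULL
  if (!is.na(p_coat) && !is.na(p_kern) &&
      p_coat - p_kern >= min_contrast_sd * noise_est) {
    cut_kc <- (p_coat + p_kern) / 2
    kern <- interior_of(msk & I >= cut_lo & I < cut_kc)
    if (!is.null(kern)) kern_cuts <- c(cut_lo, cut_kc)
  }
  if (!is.null(kern) && !is.null(kern_cuts)) {
    # boundary relaxation on raw intensities: smoothing flattens the thin
    # coat's plateau and drags the blurred class boundary into the
    # kernel; re-deciding the one-voxel boundary layer on raw values
    # re-centres it (noise-induced roughness is balanced and later
    # suppressed by mask regularisation in the thickness measurement)
    inlier <- function(m) m & !shell_border
    for (it in 1:2) {
      in_class <- I0 >= kern_cuts[1] & I0 < kern_cuts[2]
      grow <- inlier(.dilate1(kern, d) & msk & !kern & in_class)
      rim <- kern & !.erode1(kern, d)
      drop <- rim & !in_class
      kern <- (kern | grow) & !drop
    }
    lab <- array(cpp_label(c_vec(kern), d, 6L), dim = d)
    if (max(lab) > 1) kern <- lab == which.max(tabulate(lab))
  }
  if (!is.null(kern)) {
    # intensity-based candidate must show genuine tissue contrast with
    # the remaining shell (guards against splitting pure noise)
    med_k <- med(I0[kern])
    ref <- msk & !kern & dmask > 2
    if (any(ref)) {
      med_s <- med(I0[ref])
      if (abs(med_s - med_k) < min_contrast_sd * noise_est) kern <- NULL
    }
  }
  if (is.null(kern)) {
    # no usable kernel/coat contrast: rely on the cavity gap geometry
    kern <- pick_interior(msk & I >= cut1)
    if (is.null(kern)) stop("kernel not found")
  }
  kern <- array(cpp_fill_holes(c_vec(kern), d), dim = d)
  if (sum(kern) < min_size || sum(kern) > 0.98 * sum(msk))
    stop("kernel not found")
  ct_mask(kern, seed_vol$spacing_mm)
}

#' Split the shell around the kernel into coat and cavity
#'
#' The shell is the seed minus the kernel. An Otsu threshold on the shell
#' intensities, re-centred on the midpoint of the raw-intensity class
#' medians, separates the bright coat from the dark cavity; a contrast
#' guard keeps a cavity-free shell from being split by noise. Shallow dark rims confined to the outermost voxel layers are
#' partial-volume artefacts and are reassigned to the coat; dark
#' components that reach deeper are genuine cavity even when they touch
#' the surface (a breached coat, caught later by [flag_damage()]).
#'
#' @param seed_vol [ct_volume] of the extracted seed.
#' @param seed_mask [ct_mask] of the whole seed.
#' @param kernel_mask [ct_mask] from [segment_kernel()].
#' @param smooth_vox pre-smoothing box radius.
#' @param min_contrast_sd contrast guard: minimum raw-intensity class
#'   median separation in units of the estimated noise SD.
#' @return List with `coat` and `cavity` [ct_mask]s.
#' @export
segment_shell <- function(seed_vol, seed_mask, kernel_mask,
                          smooth_vox = 1L, min_contrast_sd = 2.5,
                          .blurred = NULL, .dmask = NULL) {
  stopifnot(inherits(seed_vol, "ct_volume"), inherits(seed_mask, "ct_mask"),
            inherits(kernel_mask, "ct_mask"))
  msk <- seed_mask$data
  kern <- kernel_mask$data
  if (any(kern & !msk)) stop("kernel mask not contained in seed mask")
  d <- .dims(msk)
  shell <- msk & !kern
  sp <- seed_vol$spacing_mm
  if (!any(shell))
    return(list(coat = ct_mask(shell, sp), cavity = ct_mask(shell, sp)))
  I0 <- seed_vol$data
  I <- if (is.null(.blurred))
    array(cpp_box_blur(c_vec(I0), d, as.integer(smooth_vox)), dim = d)
  else .blurred
  bl <- I[shell]
  raw <- I0[shell]
  noise_est <- stats::mad(raw - bl)
  cavity <- array(FALSE, dim = d)
  if (diff(range(bl)) > 1e-9) {
    cut <- .otsu_cut(bl, min(bl), max(bl) + 1e-12)
    for (it in 1:4) {
      hi <- bl >= cut
      if (!any(hi) || all(hi)) break
      cut <- (median(raw[!hi]) + median(raw[hi])) / 2
    }
    loc <- bl < cut
    if (any(loc) && any(!loc) &&
        (median(raw[!loc]) - median(raw[loc])) >=
          min_contrast_sd * max(noise_est, 1e-6)) {
      cavity <- shell & I < cut
      # depth classification: shallow surface rims are partial volume
      dmask <- if (is.null(.dmask)) array(cpp_edt(c_vec(msk), d), dim = d)
               else .dmask
      lab <- array(cpp_label(c_vec(cavity), d, 6L), dim = d)
      ns <- max(lab)
      if (ns > 0) {
        lv <- lab[cavity]
        sizes <- tabulate(lv, nbins = ns)
        maxdepth <- rep(0, ns)
        agg <- tapply(dmask[cavity], lv, max)
        maxdepth[as.integer(names(agg))] <- agg
        drop <- which(maxdepth <= 2.5 | sizes < 27)
        if (length(drop) > 0) cavity[lab %in% drop] <- FALSE
      }
    }
  }
  coat <- shell & !cavity
  list(coat = ct_mask(coat, sp), cavity = ct_mask(cavity, sp))
}

#' Segment a seed into kernel, coat and cavity
#'
#' Runs [segment_kernel()] and [segment_shell()] and assembles a
#' [seed_components()] object, attaching quality flags from
#' [flag_damage()].
#'
#' @inheritParams segment_kernel
#' @param flag run damage detection (default TRUE).
#' @return A `seed_components` object.
#' @export
segment_components <- function(seed_vol, seed_mask, min_frac = 0.05,
                               smooth_vox = 1L, flag = TRUE) {
  d <- .dims(seed_mask$data)
  I <- array(cpp_box_blur(c_vec(seed_vol$data), d,
                          as.integer(smooth_vox)), dim = d)
  dmask <- array(cpp_edt(c_vec(seed_mask$data), d), dim = d)
  kern <- segment_kernel(seed_vol, seed_mask, min_frac, smooth_vox,
                         .blurred = I, .dmask = dmask)
  sh <- segment_shell(seed_vol, seed_mask, kern, smooth_vox,
                      .blurred = I, .dmask = dmask)
  comp <- seed_components(seed_mask, kern, sh$coat, sh$cavity)
  if (flag) comp$flags <- flag_damage(comp, .dmask = dmask)
  comp
}

#' Detect damaged seeds
#'
#' Flags `"coat_breach"` when the cavity communicates with the outside
#' through a gap in the coat — either directly (a cavity voxel 6-adjacent
#' to the seed exterior) or via an open channel revealed by morphological
#' closing of the seed mask (an open cavity is not filled by hole filling,
#' so closing reclaims it; the threshold sits well above the closing gain
#' of the mildly concave intact seed body and well below any real cavity) — and `"fragmented_kernel"` when the kernel
#' has more than one large connected component. Flagged seeds are
#' excluded from statistics by default.
#'
#' @param comp a `seed_components` object.
#' @param close_radius_vox closing ball radius for channel detection
#'   (skipped when a well-enclosed cavity is present, since its gas can
#'   then not communicate with the outside).
#' @param breach_frac closing-added volume fraction that signals a breach.
#' @param fragment_frac minimum relative size of a second kernel component.
#' @param .blurred,.dmask optional precomputed smoothed volume / seed-mask
#'   distance transform (internal, to avoid repeated passes).
#' @return Character vector of flags (empty when intact).
#' @export
flag_damage <- function(comp, close_radius_vox = 5, breach_frac = 0.05,
                        fragment_frac = 0.1, .dmask = NULL) {
  stopifnot(inherits(comp, "seed_components"))
  d <- .dims(comp$seed_mask$data)
  flags <- character()
  msk <- comp$seed_mask$data
  cav <- comp$cavity_mask$data
  breach <- FALSE
  enclosed_cavity <- FALSE
  if (any(cav)) {
    # direct adjacency of cavity to the exterior
    out_d <- if (is.null(.dmask)) array(cpp_edt(c_vec(msk), d), dim = d)
             else .dmask  # 0 outside
    if (any(out_d[cav] <= 1)) breach <- TRUE
    else enclosed_cavity <- sum(cav) >= 0.02 * sum(msk)
  }
  if (!breach && !enclosed_cavity) {
    # open channel: closing the seed mask adds interior volume
    dil <- array(cpp_edt(c_vec(!msk), d) <= close_radius_vox, dim = d)
    clo <- array(cpp_edt(c_vec(dil), d) > close_radius_vox, dim = d)
    added <- sum(clo & !msk)
    if (added > breach_frac * sum(msk)) breach <- TRUE
  }
  if (breach) flags <- c(flags, "coat_breach")
  kern <- comp$kernel_mask$data
  if (any(kern)) {
    lab <- cpp_label(c_vec(kern), d, 26L)
    sizes <- tabulate(lab)
    big <- sum(sizes >= fragment_frac * sum(kern))
    if (big > 1) flags <- c(flags, "fragmented_kernel")
  }
  flags
}

#' Refine a seed mask by per-seed surface re-thresholding
#'
#' The global binarisation threshold of a whole scan sits slightly off the
#' centre of the surface partial-volume ramp when the background dominates
#' the histogram. Re-thresholding each seed against the midpoint between
#' its local background and coat plateau levels re-centres the surface,
#' which matters for coat thickness. The mask may move by at most two
#' voxels (the refinement region is the two-fold dilation of the input
#' mask).
#'
#' @param raw_vol [ct_volume] crop containing the seed with its original
#'   surroundings (not masked).
#' @param mask [ct_mask] initial seed mask on the same crop.
#' @param smooth_vox pre-smoothing box radius.
#' @return The refined [ct_mask] (falls back to the input when plateau
#'   levels cannot be estimated).
#' @export
refine_seed_mask <- function(raw_vol, mask, smooth_vox = 1L) {
  stopifnot(inherits(raw_vol, "ct_volume"), inherits(mask, "ct_mask"))
  msk <- mask$data
  if (!any(msk)) stop("empty mask")
  d <- .dims(msk)
  I0 <- raw_vol$data
  region <- .dilate1(.dilate1(msk, d), d)
  outside <- !region
  dmask <- array(cpp_edt(c_vec(msk), d), dim = d)
  band <- msk & dmask > 1.2 & dmask <= 2.6
  if (sum(outside) < 100 || sum(band) < 100) return(mask)
  med_bg <- median(I0[outside])
  med_coat <- median(I0[band])
  if (med_coat - med_bg < 0.1) return(mask)
  cut_surf <- (med_bg + med_coat) / 2
  I <- array(cpp_box_blur(c_vec(I0), d, as.integer(smooth_vox)), dim = d)
  seed2 <- region & I >= cut_surf
  # re-decide the boundary layer on raw intensities: smoothing erodes the
  # pole tips, where the surface is far from flat at the filter scale
  for (it in 1:2) {
    grow <- .dilate1(seed2, d) & region & !seed2 & I0 >= cut_surf
    rim <- seed2 & !.erode1(seed2, d)
    drop <- rim & I0 < cut_surf
    seed2 <- (seed2 | grow) & !drop
  }
  lab <- cpp_label(c_vec(seed2), d, 6L)
  sizes <- tabulate(lab)
  if (length(sizes) == 0) return(mask)
  seed2 <- array(lab == which.max(sizes), dim = d)
  seed2 <- array(cpp_fill_holes(c_vec(seed2), d), dim = d)
  ct_mask(seed2, mask$spacing_mm)
}
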