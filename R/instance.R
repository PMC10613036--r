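#' Otsu threshold of a 256-bin histogram
#'
#' Returns the bin index `t` (0-based, in 0..254) that maximises the
#' between-class variance of the split into bins `<= t` and `> t`. Ties are
#' broken by the smallest qualifying threshold.
#'
#' @param histogram integer vector of 256 bin counts.
#' @return The threshold bin index (0-based).
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256L) stop("`histogram` must have 256 bins")
  if (any(histogram < 0)) stop("negative bin counts")
  if (sum(histogram > 0) < 2L) stop("degenerate histogram")
  h <- as.numeric(histogram)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)[1:255]
  w1 <- n - w0
  s0 <- cumsum(h * lev)[1:255]
  mu <- sum(h * lev)
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu * w0[valid] / n - s0[valid])^2 /
    (w0[valid] * w1[valid]) * n
  which.max(bcv) - 1L
}

# Histogram of intensities over [lo, hi] in 256 equal bins.
.hist256 <- function(x, lo = 0, hi = 1) {
  b <- floor((x - lo) / (hi - lo) * 256)
  b[b < 0] <- 0
  b[b > 255] <- 255
  tabulate(b + 1L, nbins = 256L)
}

# Otsu threshold directly on intensities; returns the intensity cut so that
# foreground is x >= cut.
.otsu_cut <- function(x, lo = 0, hi = 1) {
  t <- otsu_threshold(.hist256(x, lo, hi))
  lo + (t + 1) * (hi - lo) / 256
}

.dims <- function(a) as.integer(dim(a))

#' Binarise a volume and fill internal holes
#'
#' Thresholds at the Otsu level of the volume's 256-bin histogram, removes
#' connected specks smaller than `min_size_vox`, and fills internal holes
#' (background components not 6-connected to the array border become
#' foreground).
#'
#' @param v a [ct_volume] with intensities in \[0, 1\].
#' @param min_size_vox minimum connected-component size kept, in voxels.
#' @param min_effectiveness minimum Otsu effectiveness (between-class
#'   share of the total variance); below it the volume is considered
#'   object-free noise.
#' @return A solid [ct_mask].
#' @export
binarize_fill <- function(v, min_size_vox = 1000L, min_effectiveness = 0.85) {
  stopifnot(inherits(v, "ct_volume"))
  x <- v$data
  rng <- range(x)
  cut <- .otsu_cut(x, rng[1], rng[2] + 1e-12)
  fg <- x >= cut
  if (all(fg) || !any(fg)) stop("no object")
  # Otsu effectiveness (between-class share of total variance): a unimodal
  # noise-only volume never exceeds ~0.75, a real object/background split
  # is well above 0.9
  w <- mean(fg)
  eta <- w * (1 - w) * (mean(x[fg]) - mean(x[!fg]))^2 / max(var(as.vector(x)), 1e-300)
  if (eta < min_effectiveness) stop("no object")
  d <- .dims(x)
  lab <- cpp_label(c_vec(fg), d, 26L)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_size_vox)
  if (length(keep) == 0L) stop("no object")
  fg <- array(lab %in% keep, dim = d)
  filled <- array(cpp_fill_holes(c_vec(fg), d), dim = d)
  if (all(filled)) stop("no object")
  ct_mask(filled, v$spacing_mm)
}

#' Split a mask into seed instances by 3D watershed
#'
#' Computes the Euclidean distance transform of the mask, places markers at
#' distance-transform maxima separated by at least `min_peak_distance_mm`,
#' and grows instances by marker-based watershed (priority flood on the
#' distance map, 6-connected). Components smaller than `min_size_vox` are
#' merged into the adjacent label with the largest shared boundary.
#'
#' @param m a [ct_mask].
#' @param min_peak_distance_mm minimum physical separation of watershed
#'   markers; default 2 mm (about half the smallest seed width).
#' @param min_size_vox minimum instance size in voxels.
#' @return A `seed_instances` object: integer label array (`labels`),
#'   instance `count`, per-label `sizes` and bounding `boxes`.
#' @export
split_instances <- function(m, min_peak_distance_mm = 2,
                            min_size_vox = 1000L) {
  stopifnot(inherits(m, "ct_mask"))
  if (!any(m$data)) stop("empty mask")
  d <- .dims(m$data)
  fg <- as.vector(m$data)
  dt <- cpp_edt(fg, d)
  min_dist_vox <- min_peak_distance_mm / m$spacing_mm
  peaks <- cpp_peak_markers(dt, fg, d, min_dist_vox, 2.0)
  if (length(peaks) == 0L) peaks <- which.max(dt)
  markers <- integer(prod(d))
  markers[peaks] <- seq_along(peaks)
  lab <- cpp_watershed(dt, fg, markers, d)
  lab <- .merge_small_labels(lab, d, min_size_vox)
  # relabel 1..k by decreasing size (ties: first occurrence)
  sizes <- tabulate(lab)
  ord <- order(-sizes, seq_along(sizes))
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(ord)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  lab <- array(lab, dim = d)
  bs <- cpp_label_boxes(c_vec(lab), d)
  sizes <- as.integer(bs$sizes)
  boxes <- lapply(seq_along(sizes), function(k)
    cbind(lo = bs$boxes[k, c(1, 3, 5)], hi = bs$boxes[k, c(2, 4, 6)]))
  structure(list(labels = lab, count = length(sizes), sizes = sizes,
                 boxes = boxes, spacing_mm = m$spacing_mm),
            class = "seed_instances")
}

# Merge labelled components smaller than min_size into the 6-adjacent label
# with the largest contact area.
.merge_small_labels <- function(lab, d, min_size) {
  repeat {
    sizes <- tabulate(lab)
    small <- which(sizes > 0 & sizes < min_size)
    if (length(small) == 0L || length(small) == length(sizes[sizes > 0]))
      break
    k <- small[1]
    idx <- which(lab == k)
    nb <- integer(0)
    nzy <- d[1] * d[2]
    for (off in c(1L, -1L, d[1], -d[1], nzy, -nzy)) {
      j <- idx + off
      ok <- j >= 1L & j <= length(lab)
      nb <- c(nb, lab[j[ok]])
    }
    nb <- nb[nb > 0L & nb != k]
    if (length(nb) == 0L) {
      lab[idx] <- 0L  # isolated speck: drop
    } else {
      tt <- table(nb)
      lab[idx] <- as.integer(names(tt)[which.max(tt)])
    }
  }
  lab
}

#' @export
print.seed_instances <- function(x, ...) {
  cat(sprintf("<seed_instances> %d instance(s), sizes: %s voxels\n",
              x$count, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Binary mask of one instance
#'
#' @param inst a `seed_instances` object.
#' @param label instance label in `1..count`.
#' @return A [ct_mask] over the full labelled grid.
#' @export
instance_mask <- function(inst, label) {
  stopifnot(inherits(inst, "seed_instances"))
  if (!(label %in% seq_len(inst$count))) stop("unknown label")
  ct_mask(inst$labels == label, inst$spacing_mm)
}

#' Extract one seed's sub-volume (AND with its instance mask)
#'
#' Crops to the instance bounding box (plus margin) and zeroes voxels
#' outside the instance mask, mirroring the "AND" combination of the
#' instance mask with the original image.
#'
#' @param v the [ct_volume] the instances were derived from.
#' @param inst a `seed_instances` object aligned to `v`.
#' @param label instance label in `1..count`.
#' @param margin_vox margin around the bounding box, in voxels.
#' @return A list with `volume` ([ct_volume]) and `mask` ([ct_mask]), both
#'   cropped identically.
#' @export
extract_instance <- function(v, inst, label, margin_vox = 2L) {
  stopifnot(inherits(v, "ct_volume"), inherits(inst, "seed_instances"))
  if (!identical(dim(v$data), dim(inst$labels)))
    stop("instances do not match volume shape")
  if (!(label %in% seq_len(inst$count))) stop("unknown label")
  bb <- inst$boxes[[label]]
  d <- dim(v$data)
  lo <- pmax(1L, bb[, "lo"] - as.integer(margin_vox))
  hi <- pmin(d, bb[, "hi"] + as.integer(margin_vox))
  sub <- v$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msk <- inst$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] ==
    label
  sub[!msk] <- 0
  list(volume = ct_volume(sub, v$spacing_mm, v$origin_label),
       mask = ct_mask(msk, v$spacing_mm))
}
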