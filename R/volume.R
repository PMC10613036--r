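#' Voxel volume with isotropic spacing
#'
#' A `ct_volume` is a 3D grayscale array in (z, y, x) axis order together
#' with the isotropic voxel edge length in mm. Voxel indices are 1-based in
#' R; the physical position of voxel centre `i` along an axis is
#' `(i - 1) * spacing_mm`.
#'
#' @param data 3D numeric array, intensities finite (typically in \[0, 1\]
#'   or \[0, 255\]).
#' @param spacing_mm isotropic voxel edge length in mm (> 0).
#' @param origin_label free-text provenance string.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing_mm, origin_label = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("all dims must be >= 1")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L ||
      !is.finite(spacing_mm) || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number")
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite")
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_label = origin_label),
            class = "ct_volume")
}

#' Binary voxel mask aligned to a volume
#'
#' @param data 3D logical array, same shape as its parent volume.
#' @param spacing_mm isotropic voxel edge length in mm.
#' @return An object of class `ct_mask`.
#' @export
ct_mask <- function(data, spacing_mm) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (!is.logical(data)) storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask must not contain NA")
  if (!is.numeric(spacing_mm) || spacing_mm <= 0)
    stop("`spacing_mm` must be positive")
  structure(list(data = data, spacing_mm = spacing_mm), class = "ct_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d (z,y,x), spacing %.5g mm%s\n",
              d[1], d[2], d[3], x$spacing_mm,
              if (nzchar(x$origin_label)) paste0(", ", x$origin_label) else ""))
  invisible(x)
}

#' @export
print.ct_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_mask> %d x %d x %d (z,y,x), %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' @export
dim.ct_mask <- function(x) dim(x$data)

.read_slice <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    bmp = stop("BMP slices are not supported; convert to TIFF or PNG first"),
    stop(sprintf("unsupported slice format '.%s'", ext)))
  if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
  img
}

#' Read a slice stack into a volume
#'
#' Reads all 2D grayscale images matching `pattern` in `directory`, sorts
#' them lexicographically by filename, and stacks them along the z axis.
#'
#' @param directory path containing the slice images.
#' @param pattern filename glob (e.g. `"*.tif"`).
#' @param spacing_mm isotropic voxel pitch in mm.
#' @return A [ct_volume].
#' @export
read_stack <- function(directory, pattern = "*.tif", spacing_mm) {
  files <- sort(list.files(directory, pattern = utils::glob2rx(pattern),
                           full.names = TRUE))
  if (length(files) == 0L) stop("no slices")
  slices <- lapply(files, .read_slice)
  shapes <- vapply(slices, function(s) dim(s), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("ragged stack")
  nz <- length(slices)
  ny <- shapes[1, 1]
  nx <- shapes[2, 1]
  arr <- array(0, dim = c(nz, ny, nx))
  for (i in seq_len(nz)) arr[i, , ] <- slices[[i]]
  ct_volume(arr, spacing_mm, origin_label = basename(directory))
}

#' Write a volume as a TIFF slice stack
#'
#' Writes one 8-bit grayscale TIFF per z slice plus a `metadata.txt`
#' key-value sidecar recording `spacing_mm`. Intensities are clamped to
#' \[0, 1\] and quantised to 8 bits.
#'
#' @param v a [ct_volume].
#' @param directory output directory (created if missing).
#' @param prefix slice filename prefix.
#' @return Invisibly, the vector of file paths written.
#' @export
write_stack <- function(v, directory, prefix = "slice") {
  stopifnot(inherits(v, "ct_volume"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(v$data)[1]
  ndig <- max(4L, nchar(as.character(nz)))
  paths <- character(nz)
  for (i in seq_len(nz)) {
    sl <- v$data[i, , ]
    sl[sl < 0] <- 0
    sl[sl > 1] <- 1
    paths[i] <- file.path(directory,
                          sprintf("%s_%0*d.tif", prefix, ndig, i))
    tiff::writeTIFF(sl, paths[i], bits.per.sample = 8L)
  }
  writeLines(c(sprintf("spacing_mm=%.10g", v$spacing_mm),
               sprintf("n_slices=%d", nz)),
             file.path(directory, "metadata.txt"))
  invisible(paths)
}

#' Downsample a volume by block-mean pooling
#'
#' Blocks of `factor^3` voxels are averaged (preserving partial-volume
#' information); trailing voxels that do not fill a block are dropped
#' (floor-truncated output dims). The voxel spacing is multiplied by
#' `factor`.
#'
#' @param v a [ct_volume].
#' @param factor positive integer downsampling factor.
#' @return A [ct_volume] with dims `floor(dim / factor)`.
#' @export
downsample <- function(v, factor) {
  stopifnot(inherits(v, "ct_volume"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(v)
  d <- dim(v$data)
  d2 <- d %/% factor
  if (any(d2 < 1L)) stop("volume too small for this factor")
  a <- v$data[seq_len(d2[1] * factor), seq_len(d2[2] * factor),
              seq_len(d2[3] * factor), drop = FALSE]
  dim(a) <- c(factor, d2[1], factor, d2[2], factor, d2[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(factor^3, prod(d2))
  out <- array(colMeans(a), dim = d2)
  ct_volume(out, v$spacing_mm * factor, v$origin_label)
}

.mask_bbox <- function(mask_data) {
  d <- dim(mask_data)
  idx <- which(mask_data)
  if (length(idx) == 0L) return(NULL)
  idx0 <- idx - 1L
  z <- idx0 %% d[1]
  r <- idx0 %/% d[1]
  y <- r %% d[2]
  x <- r %/% d[2]
  cbind(lo = c(min(z), min(y), min(x)) + 1L,
        hi = c(max(z), max(y), max(x)) + 1L)
}

#' Crop a volume to the bounding box of a mask
#'
#' @param v a [ct_volume].
#' @param m a [ct_mask] of the same shape.
#' @param margin_vox non-negative integer margin added on every side
#'   (clipped to the array bounds).
#' @return The cropped [ct_volume].
#' @export
crop_to_mask <- function(v, m, margin_vox = 0L) {
  stopifnot(inherits(v, "ct_volume"), inherits(m, "ct_mask"))
  if (!identical(dim(v$data), dim(m$data)))
    stop("mask shape does not match volume")
  if (margin_vox < 0) stop("`margin_vox` must be non-negative")
  bb <- .mask_bbox(m$data)
  if (is.null(bb)) stop("empty mask")
  d <- dim(v$data)
  lo <- pmax(1L, bb[, "lo"] - as.integer(margin_vox))
  hi <- pmin(d, bb[, "hi"] + as.integer(margin_vox))
  ct_volume(v$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
            v$spacing_mm, v$origin_label)
}

# Pass an array to compiled code without copying (attributes are ignored
# on the C++ side).
c_vec <- function(x) x
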