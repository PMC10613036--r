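# Patch-based learned kernel segmentation: network-style configuration,
# random patch extraction, sliding-window tiled inference with overlap
# averaging, and overlap metrics. The trainable model is a voxel-wise
# multilayer perceptron over multi-scale local intensity features; it sits
# behind the same contract as the threshold path (volume in, kernel mask
# out) and is an optional alternative to it.

#' Patch/stride configuration for tiled volumetric segmentation
#'
#' Encodes the patch geometry and training hyper-parameters of the tiled
#' segmentation path: 4 resolution levels with channel stages
#' (16, 32, 48, 64, 96), patches of 32 x 128 x 128 voxels processed with an
#' inference stride of (24, 96, 96), Dice loss, adaptive-moment
#' optimisation with learning rate 1e-4 and batch size 4.
#'
#' @param patch integer (z, y, x) patch shape; each dim must be divisible
#'   by `2^levels`.
#' @param stride integer (z, y, x) inference stride, elementwise <= patch.
#' @param channels channel counts per stage (levels + 1 values).
#' @param levels number of resolution levels.
#' @param learning_rate,batch_size,epochs training hyper-parameters.
#' @param loss loss name (informational; training uses it to monitor).
#' @return A `net_spec` object.
#' @export
net_spec <- function(patch = c(32L, 128L, 128L),
                     stride = c(24L, 96L, 96L),
                     channels = c(16L, 32L, 48L, 64L, 96L),
                     levels = 4L, learning_rate = 1e-4,
                     batch_size = 4L, epochs = 300L, loss = "dice") {
  patch <- as.integer(patch); stride <- as.integer(stride)
  if (length(patch) != 3L || length(stride) != 3L)
    stop("patch and stride must have 3 elements")
  if (any(patch %% (2L^levels) != 0L))
    stop("patch dims must be divisible by 2^levels")
  if (any(stride > patch)) stop("stride must be <= patch per axis")
  if (any(stride < 1L)) stop("stride must be >= 1")
  if (length(channels) != levels + 1L)
    stop("channels must have levels + 1 entries")
  structure(list(patch = patch, stride = stride, channels = channels,
                 levels = levels, learning_rate = learning_rate,
                 batch_size = batch_size, epochs = epochs, loss = loss),
            class = "net_spec")
}

#' Tile start offsets along one axis
#'
#' Start positions of patch windows along an axis of length `size`:
#' multiples of `stride`, with the final tile clamped to the boundary so
#' the tiles cover the axis exactly.
#'
#' @param size axis length (voxels).
#' @param patch patch length along the axis.
#' @param stride stride along the axis.
#' @return Integer vector of 0-based start offsets.
#' @export
tile_starts <- function(size, patch, stride) {
  if (size <= patch) return(0L)
  s <- seq.int(0L, size - patch, by = stride)
  as.integer(sort(unique(c(s, size - patch))))
}

#' Randomly extract patch/label pairs from a volume
#'
#' Draws `n` random patch corners (deterministic under `rng_seed`) and
#' returns volume/label patch pairs. Volumes smaller than the patch are
#' zero-padded; padded label voxels are NA and ignored in training.
#'
#' @param v a [ct_volume].
#' @param labels a [ct_mask] aligned with `v` (e.g. kernel ground truth).
#' @param n number of patches (>= 1).
#' @param rng_seed integer seed.
#' @param patch integer (z, y, x) patch shape.
#' @return List of length `n`; each element has `volume`, `labels` (with
#'   NA padding) and the 1-based `corner`.
#' @export
sample_patches <- function(v, labels, n, rng_seed = 1L,
                           patch = c(32L, 128L, 128L)) {
  stopifnot(inherits(v, "ct_volume"), inherits(labels, "ct_mask"))
  if (n < 1) stop("n must be >= 1")
  d <- dim(v$data)
  patch <- as.integer(patch)
  .with_seed(rng_seed, {
    corners <- vapply(seq_len(n), function(i) {
      vapply(1:3, function(k) {
        if (d[k] <= patch[k]) 1L
        else sample.int(d[k] - patch[k] + 1L, 1L)
      }, integer(1))
    }, integer(3))
    lapply(seq_len(n), function(i) {
      co <- corners[, i]
      pv <- array(0, dim = patch)
      pl <- array(NA, dim = patch)
      hi <- pmin(d, co + patch - 1L)
      sz <- hi - co + 1L
      pv[seq_len(sz[1]), seq_len(sz[2]), seq_len(sz[3])] <-
        v$data[co[1]:hi[1], co[2]:hi[2], co[3]:hi[3]]
      pl[seq_len(sz[1]), seq_len(sz[2]), seq_len(sz[3])] <-
        labels$data[co[1]:hi[1], co[2]:hi[2], co[3]:hi[3]]
      list(volume = pv, labels = pl, corner = co)
    })
  })
}

#' Split items into train and test sets
#'
#' @param items a list (patches, volumes, ...).
#' @param ratio train fraction (default 0.8 for the 8:2 split).
#' @param rng_seed integer seed.
#' @return List with `train` and `test` sublists.
#' @export
split_train_test <- function(items, ratio = 0.8, rng_seed = 1L) {
  n <- length(items)
  .with_seed(rng_seed, {
    ord <- sample.int(n)
    ntr <- round(n * ratio)
    list(train = items[ord[seq_len(ntr)]],
         test = items[ord[setdiff(seq_len(n), seq_len(ntr))]])
  })
}

#' Dice and IoU overlap of two masks
#'
#' Dice = 2|A∩B| / (|A|+|B|); IoU = |A∩B| / |A∪B|. Two empty masks count
#' as perfect agreement (both metrics 1).
#'
#' @param pred,truth [ct_mask]s or logical arrays of identical shape.
#' @return Named numeric: `dice`, `iou`.
#' @export
dice_iou <- function(pred, truth) {
  a <- if (inherits(pred, "ct_mask")) pred$data else pred
  b <- if (inherits(truth, "ct_mask")) truth$data else truth
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  na <- sum(a); nb <- sum(b)
  ni <- sum(a & b)
  if (na + nb == 0) return(c(dice = 1, iou = 1))
  c(dice = 2 * ni / (na + nb), iou = ni / (na + nb - ni))
}

# Multi-scale local intensity features for voxel classification:
# raw intensity, box means at radii 1/2/4, and the local SD at radius 2.
.voxel_features <- function(arr) {
  d <- .dims(arr)
  v <- as.vector(arr)
  b1 <- cpp_box_blur(v, d, 1L)
  b2 <- cpp_box_blur(v, d, 2L)
  b4 <- cpp_box_blur(v, d, 4L)
  m2 <- cpp_box_blur(v^2, d, 2L)
  sd2 <- sqrt(pmax(m2 - b2^2, 0))
  cbind(raw = v, b1 = b1, b2 = b2, b4 = b4, sd2 = sd2)
}

#' Train the voxel-classifier kernel segmenter
#'
#' Fits a single-hidden-layer perceptron (logistic output) on multi-scale
#' local intensity features of voxels sampled from random training
#' patches, balanced between kernel and non-kernel. The per-epoch Dice
#' loss (1 - Dice of the thresholded training predictions) is recorded.
#'
#' @param volumes list of [ct_volume] training scans.
#' @param kernel_masks list of [ct_mask] kernel ground truth, aligned.
#' @param n_patches total number of training patches.
#' @param patch integer patch shape.
#' @param voxels_per_patch voxels sampled per patch for the fit.
#' @param hidden hidden units.
#' @param epochs optimisation iterations.
#' @param rng_seed integer seed.
#' @param spec a [net_spec()] (stride/patch geometry for inference).
#' @return A `seedct_voxelnet` model.
#' @export
train_voxel_segmenter <- function(volumes, kernel_masks, n_patches = 200L,
                                  patch = c(16L, 48L, 48L),
                                  voxels_per_patch = 150L, hidden = 8L,
                                  epochs = 100L, rng_seed = 1L,
                                  spec = net_spec()) {
  stopifnot(length(volumes) == length(kernel_masks), length(volumes) >= 1)
  feats <- lapply(volumes, function(v) .voxel_features(v$data))
  X <- NULL; Y <- NULL
  .with_seed(rng_seed, {
    for (p in seq_len(n_patches)) {
      vi <- ((p - 1L) %% length(volumes)) + 1L
      d <- dim(volumes[[vi]]$data)
      co <- vapply(1:3, function(k) {
        if (d[k] <= patch[k]) 1L else sample.int(d[k] - patch[k] + 1L, 1L)
      }, integer(1))
      hi <- pmin(d, co + patch - 1L)
      # linear indices of the patch voxels
      zi <- co[1]:hi[1]; yi <- co[2]:hi[2]; xi <- co[3]:hi[3]
      lin <- as.vector(outer(outer(zi, (yi - 1L) * d[1], "+"),
                             (xi - 1L) * d[1] * d[2], "+"))
      lab <- as.vector(kernel_masks[[vi]]$data)[lin]
      pos <- lin[lab]; neg <- lin[!lab]
      k <- voxels_per_patch %/% 2L
      take <- c(if (length(pos) > 0) pos[sample.int(length(pos),
                                                    min(k, length(pos)))],
                if (length(neg) > 0) neg[sample.int(length(neg),
                                                    min(k, length(neg)))])
      X <- rbind(X, feats[[vi]][take, , drop = FALSE])
      Y <- c(Y, as.vector(kernel_masks[[vi]]$data)[take])
    }
    fit <- nnet::nnet(X, as.numeric(Y), size = hidden, maxit = epochs,
                      decay = 1e-4, entropy = TRUE, trace = FALSE)
    pr <- as.vector(stats::predict(fit, X)) >= 0.5
    dl <- 1 - unname(dice_iou(array(pr, c(length(pr), 1, 1)),
                              array(Y, c(length(Y), 1, 1)))["dice"])
    structure(list(fit = fit, spec = spec, loss_final = dl,
                   feature_names = colnames(X)),
              class = "seedct_voxelnet")
  })
}

#' @export
print.seedct_voxelnet <- function(x, ...) {
  cat(sprintf("<seedct_voxelnet> %d features, final Dice loss %.4f\n",
              length(x$feature_names), x$loss_final))
  invisible(x)
}

#' Sliding-window tiled inference
#'
#' Tiles the volume with the model's patch shape and stride (final tile
#' per axis clamped to the boundary), predicts a kernel probability per
#' voxel in each tile, averages overlapping predictions and thresholds at
#' 0.5. The output mask has exactly the input shape.
#'
#' @param model a `seedct_voxelnet` from [train_voxel_segmenter()].
#' @param v a [ct_volume].
#' @return [ct_mask] of the predicted kernel.
#' @export
infer_sliding <- function(model, v) {
  stopifnot(inherits(model, "seedct_voxelnet"), inherits(v, "ct_volume"))
  d <- dim(v$data)
  patch <- model$spec$patch
  stride <- model$spec$stride
  feats <- .voxel_features(v$data)
  acc <- array(0, dim = d)
  cnt <- array(0, dim = d)
  sz <- tile_starts(d[1], patch[1], stride[1])
  sy <- tile_starts(d[2], patch[2], stride[2])
  sx <- tile_starts(d[3], patch[3], stride[3])
  for (z0 in sz) for (y0 in sy) for (x0 in sx) {
    zi <- (z0 + 1L):min(d[1], z0 + patch[1])
    yi <- (y0 + 1L):min(d[2], y0 + patch[2])
    xi <- (x0 + 1L):min(d[3], x0 + patch[3])
    lin <- as.vector(outer(outer(zi, (yi - 1L) * d[1], "+"),
                           (xi - 1L) * d[1] * d[2], "+"))
    pr <- as.vector(stats::predict(model$fit,
                                   feats[lin, , drop = FALSE]))
    acc[lin] <- acc[lin] + pr
    cnt[lin] <- cnt[lin] + 1
  }
  ct_mask(acc / cnt >= 0.5, v$spacing_mm)
}
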