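# End-to-end orchestration: configuration, the scan-processing chain
# (binarise -> instances -> components -> traits -> indices), manifests,
# and the deterministic fixture set.

#' Build a pipeline run configuration
#'
#' @param mode `"phantom_population"` (one mini-scan per seed),
#'   `"phantom_scene"` (one multi-seed scene) or `"stack"` (slice stack on
#'   disk).
#' @param n_seeds number of phantom seeds (phantom modes).
#' @param population phantom population table ([default_population()]).
#' @param spacing_mm voxel pitch for phantom generation / stack reading.
#' @param rng_seed root seed; all randomness derives from it.
#' @param input_dir,pattern slice stack location (stack mode).
#' @param downsample_factor block-mean downsampling before segmentation.
#' @param min_peak_distance_mm watershed marker separation.
#' @param min_size_vox speck/instance size threshold.
#' @param component_method `"threshold"` (default) or `"voxelnet"`.
#' @param voxelnet optional trained model for the voxelnet method.
#' @param out_dir optional output directory for traits.csv, ground truth
#'   and the run manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = "phantom_population", n_seeds = 3L,
                       population = default_population(),
                       spacing_mm = 0.04, rng_seed = 1L,
                       input_dir = NULL, pattern = "*.tif",
                       downsample_factor = 1L,
                       min_peak_distance_mm = 2,
                       min_size_vox = 1000L,
                       component_method = "threshold",
                       voxelnet = NULL, out_dir = NULL) {
  cfg <- list(mode = mode, n_seeds = as.integer(n_seeds),
              population = population, spacing_mm = spacing_mm,
              rng_seed = as.integer(rng_seed), input_dir = input_dir,
              pattern = pattern,
              downsample_factor = as.integer(downsample_factor),
              min_peak_distance_mm = min_peak_distance_mm,
              min_size_vox = as.integer(min_size_vox),
              component_method = component_method, voxelnet = voxelnet,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [run_config()] can be given as `key: value` pairs; the
#' population table as a list of rows with `trait/mean/sd/lo/hi`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$population)) {
    y$population <- do.call(rbind, lapply(y$population, as.data.frame))
  }
  do.call(run_config, y)
}

# Segment one scan volume and phenotype every instance found in it.
# Returns trait rows (with indices), per-instance flags and log info.
.process_scan <- function(v, cfg, scan_id = 1L) {
  if (cfg$downsample_factor > 1L) v <- downsample(v, cfg$downsample_factor)
  rng <- range(v$data)
  thr <- .otsu_cut(v$data, rng[1], rng[2] + 1e-12)
  mask <- binarize_fill(v, min_size_vox = cfg$min_size_vox)
  inst <- split_instances(mask, cfg$min_peak_distance_mm, cfg$min_size_vox)
  rows <- NULL
  flags <- list()
  d <- dim(v$data)
  for (lab in seq_len(inst$count)) {
    # crop with context, re-centre the seed surface on its local
    # partial-volume ramp, then AND with the refined mask
    bb <- inst$boxes[[lab]]
    lo <- pmax(1L, bb[, "lo"] - 3L)
    hi <- pmin(d, bb[, "hi"] + 3L)
    raw_crop <- ct_volume(v$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                 drop = FALSE], v$spacing_mm)
    mask_crop <- ct_mask(inst$labels[lo[1]:hi[1], lo[2]:hi[2],
                                     lo[3]:hi[3], drop = FALSE] == lab,
                         v$spacing_mm)
    mask_ref <- refine_seed_mask(raw_crop, mask_crop)
    vol_and <- raw_crop
    vol_and$data[!mask_ref$data] <- 0
    ex <- list(volume = vol_and, mask = mask_ref)
    comp <- if (identical(cfg$component_method, "voxelnet") &&
                !is.null(cfg$voxelnet)) {
      kern <- infer_sliding(cfg$voxelnet, ex$volume)
      kern$data <- kern$data & ex$mask$data
      sh <- segment_shell(ex$volume, ex$mask, kern)
      cmp <- seed_components(ex$mask, kern, sh$coat, sh$cavity)
      cmp$flags <- flag_damage(cmp)
      cmp
    } else {
      segment_components(ex$volume, ex$mask)
    }
    flags[[lab]] <- comp$flags
    if (length(comp$flags) == 0) {
      tr <- compute_traits(comp, seed_id = lab)
      tr$scan_id <- scan_id
      rows <- rbind(rows, tr)
    }
  }
  if (!is.null(rows)) rows <- compute_indices(rows)
  list(traits = rows, flags = flags, threshold = thr,
       instance_count = inst$count)
}

#' Run the full phenotyping pipeline
#'
#' Executes read/generate -> downsample -> instance segmentation ->
#' component segmentation -> trait extraction -> indices, and (optionally)
#' writes `traits.csv`, `ground_truth.csv` and a JSON manifest recording
#' every parameter, seed, automatically chosen threshold and per-stage
#' timing needed to re-run the analysis.
#'
#' @param cfg a [run_config()].
#' @return List with `traits` (data.frame incl. the three indices),
#'   `ground_truth` (phantom modes), `flags`, and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  gt <- NULL
  traits <- NULL
  flags <- list()
  thresholds <- numeric(0)
  counts <- integer(0)
  gen_time <- 0
  if (cfg$mode == "phantom_population") {
    # one mini-scan per seed, generated and processed in a stream so that
    # only one volume is resident at a time
    specs <- sample_specs(cfg$population, cfg$n_seeds,
                          rng_seed = cfg$rng_seed)
    for (i in seq_along(specs)) {
      tg <- proc.time()[["elapsed"]]
      ph <- make_seed(specs[[i]], spacing_mm = cfg$spacing_mm,
                      gt_areas = FALSE)
      ph$ground_truth$seed_id <- i
      gt <- rbind(gt, ph$ground_truth)
      gen_time <- gen_time + proc.time()[["elapsed"]] - tg
      res <- .process_scan(ph$volume, cfg, scan_id = i)
      rm(ph)
      if (!is.null(res$traits)) {
        res$traits$seed_id <- i
        traits <- rbind(traits, res$traits)
      }
      flags[[i]] <- res$flags
      thresholds[i] <- res$threshold
      counts[i] <- res$instance_count
    }
  } else {
    scan <- if (cfg$mode == "stack") {
      if (is.null(cfg$input_dir)) stop("stack mode needs input_dir")
      read_stack(cfg$input_dir, cfg$pattern, cfg$spacing_mm)
    } else if (cfg$mode == "phantom_scene") {
      specs <- sample_specs(cfg$population, cfg$n_seeds,
                            rng_seed = cfg$rng_seed)
      sc <- make_scene(specs, spacing_mm = cfg$spacing_mm,
                       rng_seed = cfg$rng_seed + 1000L)
      gt <- sc$ground_truth
      sc$volume
    } else stop("unknown mode: ", cfg$mode)
    gen_time <- proc.time()[["elapsed"]] - t0
    res <- .process_scan(scan, cfg, scan_id = 1L)
    traits <- res$traits
    flags[[1]] <- res$flags
    thresholds <- res$threshold
    counts <- res$instance_count
  }
  timings["generate_or_read"] <- gen_time
  timings["segment_and_phenotype"] <-
    proc.time()[["elapsed"]] - t0 - gen_time

  manifest <- list(
    package = "seedct",
    version = as.character(utils::packageVersion("seedct")),
    r_version = R.version.string,
    config = cfg[setdiff(names(cfg), c("voxelnet", "population"))],
    population = if (!is.null(cfg$population)) cfg$population,
    otsu_thresholds = thresholds,
    instance_counts = counts,
    n_flagged = sum(vapply(flags, function(f)
      sum(lengths(f) > 0), integer(1))),
    timings_sec = as.list(round(timings, 3)))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(traits))
      write.csv(traits, file.path(cfg$out_dir, "traits.csv"),
                row.names = FALSE)
    if (!is.null(gt))
      write.csv(gt, file.path(cfg$out_dir, "ground_truth.csv"),
                row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(traits = traits, ground_truth = gt, flags = flags,
       manifest = manifest)
}

#' Phantom seed with a drilled coat breach
#'
#' Renders a seed and carves a cylindrical channel through the coat from
#' the cavity pole outward, so the cavity communicates with the outside
#' air; used to exercise damage detection.
#'
#' @param spec a `seed_spec`.
#' @param spacing_mm voxel pitch.
#' @param hole_radius_mm channel radius.
#' @return As [make_seed()]; the ground-truth masks contain the breach.
#' @export
make_breached_seed <- function(spec, spacing_mm = 0.04,
                               hole_radius_mm = 0.15) {
  r <- .render_seed(spec, spacing_mm)
  dims <- r$dims
  geo <- r$geo
  wz <- .axis_sum(geo$gz, rep(0, dims[2]), rep(0, dims[3]))
  wy <- .axis_sum(rep(0, dims[1]), geo$gy, rep(0, dims[3]))
  wx <- .axis_sum(rep(0, dims[1]), rep(0, dims[2]), geo$gx)
  pole <- spec$cavity_pole
  if (any(r$cavity_bin)) {
    ctr <- c(mean(wz[r$cavity_bin]), mean(wy[r$cavity_bin]),
             mean(wx[r$cavity_bin]))
  } else ctr <- c(0, 0, 0)
  s <- (wz - ctr[1]) * pole[1] + (wy - ctr[2]) * pole[2] +
    (wx - ctr[3]) * pole[3]
  rad2 <- (wz - ctr[1] - s * pole[1])^2 + (wy - ctr[2] - s * pole[2])^2 +
    (wx - ctr[3] - s * pole[3])^2
  chan <- array(s > 0 & rad2 < hole_radius_mm^2, dim = dims)
  drill <- chan & (r$coat_bin | (r$seed_bin & !r$kernel_bin & !r$cavity_bin))
  r$O[drill] <- 0
  r$contrib[drill] <- 0
  r$seed_bin <- r$seed_bin & !drill
  r$coat_bin <- r$coat_bin & !drill
  ii <- spec$intensities
  img <- ii$background * (1 - as.vector(r$O)) + as.vector(r$contrib)
  if (spec$noise_sd > 0)
    img <- .with_seed(spec$rng_seed,
                      img + rnorm(length(img), 0, spec$noise_sd))
  img <- pmin(1, pmax(0, img))
  masks <- list(seed = ct_mask(r$seed_bin, spacing_mm),
                kernel = ct_mask(r$kernel_bin, spacing_mm),
                coat = ct_mask(r$coat_bin, spacing_mm),
                cavity = ct_mask(r$cavity_bin, spacing_mm))
  list(volume = ct_volume(array(img, dim = dims), spacing_mm,
                          "phantom (breached)"),
       masks = masks, ground_truth = .ground_truth_row(r, spec),
       spec = spec)
}

#' Write the deterministic phantom fixture set
#'
#' One intact seed, one cavity-free seed, one breached seed and one
#' three-seed scene, written as TIFF stacks (plus label stacks and a
#' ground-truth CSV of all 6 seeds) under `dir`. Byte-identical on repeat
#' calls with the same seed.
#'
#' @param dir output directory.
#' @param rng_seed integer seed.
#' @param spacing_mm voxel pitch (coarser than scans, to keep fixtures
#'   small).
#' @return Invisibly, a list with the generated objects and paths.
#' @export
make_fixtures <- function(dir = file.path(tempdir(), "seedct-fixtures"),
                          rng_seed = 1L, spacing_mm = 0.08) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- default_population()
  pop$sd <- rep(0, nrow(pop))
  specs <- sample_specs(pop, 3, rng_seed = rng_seed)
  intact <- make_seed(specs[[1]], spacing_mm)
  zc_spec <- specs[[2]]
  zc_spec$target_fullness <- NA
  zero_cavity <- make_seed(zc_spec, spacing_mm)
  breached <- make_breached_seed(specs[[3]], spacing_mm,
                                 hole_radius_mm = 0.2)
  scene <- make_scene(specs, spacing_mm = spacing_mm,
                      rng_seed = rng_seed + 7L)
  write_stack(intact$volume, file.path(dir, "intact"))
  write_stack(zero_cavity$volume, file.path(dir, "zero_cavity"))
  write_stack(breached$volume, file.path(dir, "breached"))
  write_stack(scene$volume, file.path(dir, "scene"))
  write_stack(ct_volume(array(scene$labels / max(scene$labels),
                              dim = dim(scene$labels)),
                        spacing_mm, "labels"),
              file.path(dir, "scene_labels"))
  gt <- rbind(cbind(fixture = "intact", intact$ground_truth),
              cbind(fixture = "zero_cavity", zero_cavity$ground_truth),
              cbind(fixture = "breached", breached$ground_truth),
              cbind(fixture = "scene", scene$ground_truth))
  write_ground_truth(gt, file.path(dir, "ground_truth.csv"))
  invisible(list(dir = dir, intact = intact, zero_cavity = zero_cavity,
                 breached = breached, scene = scene, ground_truth = gt))
}
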