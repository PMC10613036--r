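# Shared fixtures, generated in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small, quick-to-render seed used by most unit tests
small_spec <- function(fullness = 0.5, rng_seed = 1L, noise_sd = 0.04,
                       ...) {
  seed_spec(semi_axes_mm = c(2.2, 1.5, 1.3), coat_thickness_mm = 0.18,
            target_fullness = fullness, rng_seed = rng_seed,
            noise_sd = noise_sd, ...)
}

small_seed <- function() {
  cached("small_seed", make_seed(small_spec(), spacing_mm = 0.06))
}

# a mean-parameter seed of the default population, random orientation
mean_spec <- function(rng_seed = 5L) {
  pop <- default_population()
  pop$sd <- rep(0, nrow(pop))
  sample_specs(pop, 1, rng_seed = rng_seed)[[1]]
}

# volume restricted to a ground-truth seed mask (the per-seed "AND" input
# for component segmentation on the uncropped grid)
masked_volume <- function(ph) {
  v <- ph$volume
  v$data[!ph$masks$seed$data] <- 0
  v
}

# the 102-seed threshold-path population used by the acceptance criteria
# (and reused by the statistics agreement check); one shared run
acceptance_population <- function() {
  cached("acceptance_population", {
    run_pipeline(run_config(mode = "phantom_population", n_seeds = 102L,
                            spacing_mm = 0.05, rng_seed = 1L))
  })
}

expect_dice_at_least <- function(pred, truth, floor) {
  d <- unname(dice_iou(pred, truth)["dice"])
  expect_gte(d, floor)
  invisible(d)
}
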