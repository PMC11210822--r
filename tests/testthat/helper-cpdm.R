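# Shared fixtures and a cache for the expensive benchmark runs, so several
# acceptance checks can share one computation.

bench_cache <- new.env(parent = emptyenv())

# Benchmark protocol for the soft table checks: 10 samples, stride 2,
# r1 = r2 = 10, M = 20, and the default hyperparameter grids with the h
# axis subsampled evenly to {20, 60, 120, 200} to keep the run at desk
# scale.
scaled_default_grids <- function() {
  list(h = c(20L, 60L, 120L, 200L), r_hat = 1:10,
       alpha = c(0.1, 0.5, 1, 10), k = 1:10)
}

table1_benchmark <- function(family = c("mean_shift", "variance_shift")) {
  family <- match.arg(family)
  key <- paste0("bm_", family)
  if (!exists(key, envir = bench_cache)) {
    ds <- switch(family,
                 mean_shift = mean_shift_dataset(seed = 42),
                 variance_shift = variance_shift_dataset(seed = 43))
    bm <- cpd_benchmark(ds,
                        methods = c("cpd_dm", "hotelling_t2", "knn", "sst"),
                        grids = scaled_default_grids(), M = 20L, stride = 2L,
                        r1 = 10L, r2 = 10L)
    assign(key, bm, envir = bench_cache)
  }
  get(key, envir = bench_cache)
}

summary_metric <- function(bm, method, col) {
  bm$summary[bm$summary$method == method, col]
}

# Small random point cloud (columns are points).
random_points <- function(h, r, seed) {
  set.seed(seed)
  matrix(rnorm(h * r), h, r)
}

# Random diffusion operator from a self-tuning graph on a random cloud.
random_operator <- function(r = 10L, h = 5L, seed = 1L, alpha = 1,
                            K = 3L) {
  pts <- random_points(h, r, seed)
  diffusion_operator(affinity(pts, local_scales(pts, K)), alpha = alpha)
}
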