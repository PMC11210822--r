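#' Benchmark change-point methods on a labelled dataset
#'
#' Runs a per-sample hyperparameter grid search (maximising the margin AUC)
#' for each requested method on every sample of a labelled dataset, and
#' summarises the per-sample metrics as mean and SD per method — the layout
#' of a benchmark results table.
#'
#' @param dataset A `"cpd_dataset"` (e.g. from [mean_shift_dataset()]).
#' @param methods Character vector of methods, as in [cpd()].
#' @param grids Hyperparameter grids, as in [grid_search_best_auc()].
#' @param M Margin in points (default 20).
#' @param stride Evaluation step.
#' @param r1,r2 Window column counts (`NULL` for the per-`h` default).
#' @param K,k_map Diffusion-map neighbour parameters.
#' @param normalize Range-normalise each sample first? (default TRUE)
#' @param threshold_mult Detection threshold multiplier.
#' @return An object of class `"cpd_benchmark"`: `per_sample` (one row per
#'   sample x method with the winning configuration and its metrics),
#'   `summary` (mean and SD per method and metric) and the run settings.
#' @export
cpd_benchmark <- function(dataset,
                          methods = c("cpd_dm", "hotelling_t2", "knn", "sst"),
                          grids = list(), M = 20L, stride = 1L,
                          r1 = NULL, r2 = NULL, K = 7L, k_map = 7L,
                          normalize = TRUE, threshold_mult = 1) {
  stopifnot(inherits(dataset, "cpd_dataset"))
  methods <- match.arg(methods, c("cpd_dm", "hotelling_t2", "knn", "sst"),
                       several.ok = TRUE)
  rows <- list()
  for (s in seq_along(dataset$series)) {
    X <- dataset$series[[s]]
    tau <- dataset$truths[[s]]
    for (mth in methods) {
      gs <- grid_search_best_auc(X, tau, method = mth, grids = grids, M = M,
                                 stride = stride, r1 = r1, r2 = r2, K = K,
                                 k_map = k_map, normalize = normalize,
                                 min_sep = M, threshold_mult = threshold_mult)
      p <- gs$best_params
      r <- gs$result
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, method = mth, h = p$h,
        r_hat = if (!is.null(p$r_hat)) p$r_hat else NA_integer_,
        alpha = if (!is.null(p$alpha)) p$alpha else NA_real_,
        k = if (!is.null(p$k)) p$k else NA_integer_,
        auc = r$auc, precision = r$precision, recall = r$recall,
        f1 = r$f1, rand_index = r$rand_index,
        n_detected = length(r$changepoints))
    }
  }
  per_sample <- do.call(rbind, rows)
  metrics <- c("auc", "f1", "rand_index", "precision", "recall")
  summ <- do.call(rbind, lapply(split(per_sample, per_sample$method),
    function(d) {
      out <- data.frame(method = d$method[1], n_samples = nrow(d))
      for (mt in metrics) {
        out[[paste0(mt, "_mean")]] <- mean(d[[mt]])
        out[[paste0(mt, "_sd")]] <- stats::sd(d[[mt]])
      }
      out
    }))
  summ <- summ[match(methods, summ$method), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(per_sample = per_sample, summary = summ,
                 settings = list(methods = methods, grids = grids, M = M,
                                 stride = stride, r1 = r1, r2 = r2, K = K,
                                 k_map = k_map, normalize = normalize,
                                 threshold_mult = threshold_mult,
                                 dataset_spec = dataset$spec)),
            class = "cpd_benchmark")
}

#' @export
print.cpd_benchmark <- function(x, digits = 3, ...) {
  cat(sprintf("Benchmark on %s dataset (%d sample(s), M = %d)\n",
              x$settings$dataset_spec$kind,
              length(unique(x$per_sample$sample)), x$settings$M))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s AUC %.3f +/- %.3f | F1 %.3f +/- %.3f | RI %.3f +/- %.3f\n",
                s$method[i], s$auc_mean[i], s$auc_sd[i], s$f1_mean[i],
                s$f1_sd[i], s$rand_index_mean[i], s$rand_index_sd[i]))
  }
  invisible(x)
}

#' Noise-robustness sweep over Gaussian noise levels
#'
#' Adds i.i.d. Gaussian noise of SD `sigma_hat` to every (raw) sample of the
#' dataset, re-runs [cpd_benchmark()] at each noise level, and collects a
#' metric-versus-noise table. `sigma_hat = 0` reproduces the no-noise
#' benchmark.
#'
#' @param dataset A `"cpd_dataset"` (raw, un-normalised series; the
#'   benchmark normalises after noise injection).
#' @param sigma_hat Noise SDs to sweep (default `0.1, 0.2, ..., 1.0`).
#' @param seed Integer seed for the noise draws (one derived seed per
#'   level, so levels are independent but reproducible).
#' @inheritParams cpd_benchmark
#' @return A list of class `"cpd_noise_sweep"` with `table` (one row per
#'   `sigma_hat` x method with mean metrics) and the per-level benchmark
#'   objects in `runs`.
#' @export
noise_sweep <- function(dataset, sigma_hat = seq(0.1, 1, by = 0.1),
                        methods = c("cpd_dm", "knn", "sst"),
                        grids = list(), M = 20L, stride = 1L,
                        r1 = NULL, r2 = NULL, K = 7L, k_map = 7L,
                        seed = 1L, threshold_mult = 1) {
  stopifnot(inherits(dataset, "cpd_dataset"))
  if (any(sigma_hat < 0)) stop("`sigma_hat` values must be >= 0")
  runs <- list()
  rows <- list()
  for (i in seq_along(sigma_hat)) {
    sg <- sigma_hat[i]
    noisy <- dataset
    for (s in seq_along(noisy$series))
      noisy$series[[s]] <- add_gaussian_noise(
        dataset$series[[s]], sg, seed = seed + 1000L * i + s)
    bm <- cpd_benchmark(noisy, methods = methods, grids = grids, M = M,
                        stride = stride, r1 = r1, r2 = r2, K = K,
                        k_map = k_map, threshold_mult = threshold_mult)
    runs[[i]] <- bm
    tb <- bm$summary
    tb$sigma_hat <- sg
    rows[[i]] <- tb
  }
  tab <- do.call(rbind, rows)
  tab <- tab[, c("sigma_hat", setdiff(names(tab), "sigma_hat"))]
  rownames(tab) <- NULL
  structure(list(table = tab, runs = runs,
                 settings = list(sigma_hat = sigma_hat, methods = methods,
                                 grids = grids, M = M, stride = stride,
                                 seed = seed)),
            class = "cpd_noise_sweep")
}

#' @export
print.cpd_noise_sweep <- function(x, ...) {
  cat("Noise sweep (mean AUC by sigma_hat):\n")
  print(x$table[, c("sigma_hat", "method", "auc_mean", "f1_mean",
                    "rand_index_mean")], row.names = FALSE)
  invisible(x)
}

#' Plot a noise sweep as metric-versus-noise lines
#'
#' @param x A `"cpd_noise_sweep"`.
#' @param metric Which mean metric column to draw (default `"auc_mean"`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cpd_noise_sweep <- function(x, metric = "auc_mean", ...) {
  tab <- x$table
  methods <- unique(tab$method)
  cols <- c(cpd_dm = "red3", hotelling_t2 = "blue3", knn = "green4",
            sst = "cyan4")
  graphics::plot(range(tab$sigma_hat), range(tab[[metric]], na.rm = TRUE),
                 type = "n", xlab = "noise SD", ylab = metric, ...)
  for (mth in methods) {
    d <- tab[tab$method == mth, ]
    graphics::lines(d$sigma_hat, d[[metric]], type = "b",
                    col = if (mth %in% names(cols)) cols[[mth]] else "black")
  }
  graphics::legend("bottomleft", legend = methods, lty = 1,
                   col = ifelse(methods %in% names(cols), cols[methods],
                                "black"), bty = "n")
  invisible(x)
}
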