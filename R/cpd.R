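#' Change-point scoring of a (multichannel) time series
#'
#' Fits a change-score series to a time series with one of four methods:
#'
#' * `"cpd_dm"` — diffusion-map change-point detection. At each evaluation
#'   time the past Hankel window `P` is embedded with a diffusion map built
#'   on a self-tuning Gaussian affinity graph over its columns; the current
#'   window `Q` is mapped into the same embedding by a k-nearest-neighbour
#'   affine out-of-sample extension, and the score is the Frobenius norm of
#'   the difference between the two embedded windows.
#' * `"sst"` — singular spectrum transformation:
#'   `1 - sigma_max(U' Z)^2` for the top `r_hat` left singular vectors `U`,
#'   `Z` of `P` and `Q` (in `[0, 1]`).
#' * `"hotelling_t2"` — Hotelling's T-squared distance between the column
#'   means of `Q` and `P` under `P`'s (ridge-regularised) column covariance.
#' * `"knn"` — mean over `Q`'s columns of the average distance to each
#'   column's `k` nearest columns of `P`.
#'
#' Scores are computed on the evaluation grid
#' `seq(r1 + h, N - lag + 1, by = stride)` (1-based); time points without
#' full history/horizon are left undefined (`NA`), never zero-filled.
#'
#' @param x Series: numeric vector, matrix or data frame (rows = time,
#'   columns = channels).
#' @param method One of `"cpd_dm"`, `"sst"`, `"hotelling_t2"`, `"knn"`.
#' @param h Window size in points.
#' @param r1,r2 Window column counts; default `max(2, floor(h/2))`, and
#'   `r1 == r2` is required for `"cpd_dm"`.
#' @param lag Lag `L` between past and current windows; default
#'   `floor(h/4)`.
#' @param stride Evaluation step in points.
#' @param r_hat Embedded dimension (`"cpd_dm"`, `"sst"`).
#' @param alpha Diffusion time (`"cpd_dm"`); fractional values allowed.
#' @param K Neighbour rank for the self-tuning kernel scales (default 7).
#' @param k_map Neighbour count for the out-of-sample extension (default 7).
#' @param k Neighbour count for the `"knn"` score.
#' @param normalize Apply per-channel `[0, 1]` range normalisation first?
#' @param kernel_two_factor Keep the factor 2 in the Gaussian kernel
#'   denominator (see [affinity()])?
#' @return An object of class `"cpd"`: a list with `scores` (length-`N`
#'   vector, `NA` outside the valid range), `t_eval`, `valid_range`,
#'   `method`, `params`, `config`, the analysed `series`, `N`, `m` and the
#'   matched `call`.
#' @seealso [detect_change_points()], [evaluate_scores()],
#'   [grid_search_best_auc()]
#' @examples
#' x <- step_fixture(N = 200, tau = 100, amplitude = 5)
#' fit <- cpd(x$series[[1]], method = "cpd_dm", h = 20, lag = 5, r_hat = 2)
#' fit
#' which.max(fit$scores)
#' @export
cpd <- function(x,
                method = c("cpd_dm", "sst", "hotelling_t2", "knn"),
                h = 20L, r1 = NULL, r2 = NULL, lag = NULL, stride = 1L,
                r_hat = 2L, alpha = 1, K = 7L, k_map = 7L, k = 5L,
                normalize = TRUE, kernel_two_factor = TRUE) {
  method <- match.arg(method)
  X <- as_series_matrix(x)
  if (normalize) X <- range_normalize(X)
  cfg <- window_config(h = h, r1 = r1, r2 = r2, lag = lag, stride = stride)
  scan <- switch(method,
    cpd_dm = scan_cpd_dm(X, cfg, r_hat_grid = r_hat, alpha_grid = alpha,
                         K = K, k_map = k_map,
                         kernel_two_factor = kernel_two_factor),
    sst = scan_sst(X, cfg, r_hat_grid = r_hat),
    hotelling_t2 = scan_hotelling_t2(X, cfg),
    knn = scan_knn(X, cfg, k_grid = k))
  scores <- rep(NA_real_, nrow(X))
  if (length(scan$t_eval)) scores[scan$t_eval] <- scan$scores[, 1L]
  params <- switch(method,
    cpd_dm = list(r_hat = r_hat, alpha = alpha, K = K, k_map = k_map,
                  kernel_two_factor = kernel_two_factor),
    sst = list(r_hat = r_hat),
    hotelling_t2 = list(),
    knn = list(k = k))
  structure(list(scores = scores, t_eval = scan$t_eval,
                 valid_range = valid_time_range(nrow(X), cfg),
                 method = method, params = params, config = cfg,
                 series = X, N = nrow(X), m = ncol(X),
                 normalized = normalize, call = match.call()),
            class = "cpd")
}

#' @export
print.cpd <- function(x, ...) {
  cat(sprintf("Change-point score series (method: %s)\n", x$method))
  cat(sprintf("  series: %d time points x %d channel(s)%s\n", x$N, x$m,
              if (isTRUE(x$normalized)) ", range-normalized" else ""))
  cat(sprintf("  windows: h = %d, r1 = %d, r2 = %d, lag = %d, stride = %d\n",
              x$config$h, x$config$r1, x$config$r2, x$config$lag,
              x$config$stride))
  if (length(x$params))
    cat("  params:",
        paste(names(x$params),
              vapply(x$params, function(v) format(v)[1], character(1)),
              sep = " = ", collapse = ", "), "\n")
  n_def <- sum(is.finite(x$scores))
  if (n_def) {
    cat(sprintf("  %d scores defined on t in [%d, %d]; max %.4g at t = %d\n",
                n_def, x$valid_range[1], x$valid_range[2],
                max(x$scores, na.rm = TRUE), which.max(x$scores)))
  } else {
    cat("  no defined scores (series shorter than r1 + h + lag)\n")
  }
  invisible(x)
}

#' @export
summary.cpd <- function(object, min_sep = 20L, threshold_mult = 1, ...) {
  cps <- detect_change_points(object, min_sep = min_sep,
                              threshold_mult = threshold_mult)
  out <- list(fit = object, changepoints = cps,
              score_summary = summary(object$scores[object$t_eval]))
  class(out) <- "summary.cpd"
  out
}

#' @export
print.summary.cpd <- function(x, ...) {
  print(x$fit)
  cat("  score summary:\n")
  print(x$score_summary)
  r <- attr(x$changepoints, "rule")
  cat(sprintf("  detected change points (mean + %g SD, min separation %d):\n",
              r$threshold_mult, r$min_sep))
  if (length(x$changepoints)) print(as.integer(x$changepoints)) else cat("    none\n")
  invisible(x)
}

#' Plot a change-score series over the first channel
#'
#' Two stacked panels: the first channel of the analysed series, and the
#' change-score series with detected change points (dashed) and optional
#' true change points (dotted).
#'
#' @param x A fitted [cpd()] object.
#' @param true_cps Optional integer vector of true change points.
#' @param min_sep,threshold_mult Detection rule, as in
#'   [detect_change_points()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cpd <- function(x, true_cps = NULL, min_sep = 20L, threshold_mult = 1,
                     ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$series[, 1L], type = "l", ylab = "channel 1",
                 xlab = "", main = paste("method:", x$method), ...)
  if (!is.null(true_cps))
    graphics::abline(v = true_cps, lty = 3, col = "grey40")
  graphics::plot(x$scores, type = "l", col = "red3", ylab = "change score",
                 xlab = "t")
  if (!is.null(true_cps))
    graphics::abline(v = true_cps, lty = 3, col = "grey40")
  cps <- detect_change_points(x, min_sep = min_sep,
                              threshold_mult = threshold_mult)
  if (length(cps)) graphics::abline(v = cps, lty = 2, col = "blue3")
  invisible(x)
}
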