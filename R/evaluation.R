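#' True positives among ground-truth change points
#'
#' A true change point counts as detected when at least one predicted point
#' lies strictly within the margin: `TP = { tau_i : exists tau_hat_j with
#' |tau_hat_j - tau_i| < M }`.
#'
#' @param tau Sorted true change-point indices.
#' @param tau_hat Predicted change-point indices (may be empty).
#' @param M Margin in time points.
#' @return The subset of `tau` with a prediction within the margin.
#' @export
true_positive_set <- function(tau, tau_hat, M) {
  tau <- as.integer(tau)
  if (length(tau_hat) == 0L) return(integer(0))
  tau[vapply(tau, function(z) any(abs(tau_hat - z) < M), logical(1))]
}

#' Margin-based precision, recall and F1 of detected change points
#'
#' `precision = |TP| / n_hat`, `recall = |TP| / n`,
#' `F1 = 2 P R / (P + R)`, with the conventions `precision = 0` when no
#' points were predicted and `F1 = 0` when both components are 0. Note that
#' precision divides by the number of *predictions*: two predictions near
#' one true point still count as one true positive, so the second one costs
#' precision.
#'
#' @inheritParams true_positive_set
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(tau, tau_hat, M) {
  n <- length(tau)
  if (n == 0L) stop("no ground-truth change points to evaluate against")
  tp <- length(true_positive_set(tau, tau_hat, M))
  n_hat <- length(tau_hat)
  precision <- if (n_hat == 0L) 0 else tp / n_hat
  recall <- tp / n
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

# Mid-rank AUC of scores against binary labels.
auc_rank <- function(s, lab) {
  keep <- is.finite(s)
  s <- s[keep]; lab <- lab[keep]
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0L) stop("margin AUC undefined: class 1 (near a change point) is empty")
  if (n0 == 0L) stop("margin AUC undefined: class 0 (background) is empty")
  r <- rank(s)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Margin-labelled ROC AUC of a change-score series
#'
#' Each evaluated time point is labelled 1 when it lies within the closed
#' margin `[tau_i - M, tau_i + M]` of some true change point and 0
#' otherwise; the AUC is the mid-rank (Mann-Whitney) statistic of the scores
#' against these labels. Undefined scores are excluded.
#'
#' @param scores A fitted [cpd()] object, or a numeric score vector.
#' @param tau True change-point indices.
#' @param M Margin in time points.
#' @param t Evaluation times matching a numeric `scores` vector.
#' @return AUC in `[0, 1]`.
#' @export
margin_auc <- function(scores, tau, M, t = NULL) {
  if (inherits(scores, "cpd")) {
    t <- scores$t_eval
    s <- scores$scores[t]
  } else {
    s <- as.numeric(scores)
    if (is.null(t)) t <- seq_along(s)
    if (length(t) != length(s)) stop("`t` must match `scores` in length")
  }
  lab <- margin_labels(t, tau, M)
  auc_rank(s, lab)
}

margin_labels <- function(t, tau, M) {
  vapply(t, function(z) any(abs(tau - z) <= M), logical(1))
}

#' Rand index of two change-point segmentations
#'
#' Each of the `N` time points is labelled by its segment under the true and
#' the predicted change points (a change point is the first index of its new
#' segment); the Rand index is the fraction of the `choose(N, 2)` point
#' pairs on which the two segmentations agree (same segment in both, or
#' different in both), computed from the segment-overlap contingency table.
#'
#' @param tau True change-point indices (sorted).
#' @param tau_hat Predicted change-point indices.
#' @param N Series length (`>= 2`).
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(tau, tau_hat, N) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("`N` must be an integer >= 2")
  a <- findInterval(seq_len(N), sort(as.integer(tau)))
  b <- findInterval(seq_len(N), sort(as.integer(tau_hat)))
  tab <- table(a, b)
  total <- choose(N, 2)
  dis <- (sum(rowSums(tab)^2) + sum(colSums(tab)^2)) / 2 - sum(tab^2)
  1 - dis / total
}

#' Evaluate a change-score series against ground truth
#'
#' Computes the margin AUC of the scores, detects change points with
#' [detect_change_points()], and scores the detections with margin-based
#' precision/recall/F1 and the Rand index of the induced segmentations.
#'
#' @param fit A fitted [cpd()] object.
#' @param tau True change-point indices.
#' @param M Margin in time points (default 20).
#' @param min_sep Minimum separation for detection (default `M`).
#' @param threshold_mult Detection threshold multiplier (default 1).
#' @return A list of class `"cpd_eval"` with `auc`, `precision`, `recall`,
#'   `f1`, `rand_index`, `M`, `changepoints` and `params`.
#' @export
evaluate_scores <- function(fit, tau, M = 20L, min_sep = M,
                            threshold_mult = 1) {
  stopifnot(inherits(fit, "cpd"))
  auc <- margin_auc(fit, tau, M)
  cps <- detect_change_points(fit, min_sep = min_sep,
                              threshold_mult = threshold_mult)
  prf <- precision_recall_f1(tau, cps, M)
  ri <- rand_index(tau, cps, fit$N)
  structure(list(auc = auc, precision = unname(prf["precision"]),
                 recall = unname(prf["recall"]), f1 = unname(prf["f1"]),
                 rand_index = ri, M = M, changepoints = cps,
                 params = c(list(method = fit$method, h = fit$config$h,
                                 r1 = fit$config$r1, r2 = fit$config$r2,
                                 lag = fit$config$lag,
                                 stride = fit$config$stride), fit$params)),
            class = "cpd_eval")
}

#' @export
print.cpd_eval <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f | precision %.3f | recall %.3f | F1 %.3f | Rand index %.3f (M = %d)\n",
    x$auc, x$precision, x$recall, x$f1, x$rand_index, x$M))
  invisible(x)
}

#' Default hyperparameter grids
#'
#' Window sizes 20, 40, ..., 200; embedded dimensions 1..10; diffusion times
#' 0.1, 0.5, 1, 10; neighbour counts 1..10.
#'
#' @return Named list of grids `h`, `r_hat`, `alpha`, `k`.
#' @export
default_grids <- function() {
  list(h = seq(20L, 200L, by = 20L), r_hat = 1:10,
       alpha = c(0.1, 0.5, 1, 10), k = 1:10)
}

#' Grid search maximising the margin AUC
#'
#' Evaluates every hyperparameter combination of the grids relevant to the
#' method (`h` always, plus `r_hat`/`alpha` for CPD-DM, `r_hat` for SST,
#' `k` for KNN), with the lag derived as `floor(h/4)` at each grid point,
#' and returns the configuration with the highest margin AUC. Ties are
#' broken towards smaller `h`, then smaller `r_hat`/`k`, then smaller
#' `alpha`. F1 and Rand index are reported at the winning configuration via
#' [detect_change_points()].
#'
#' @param x Series (vector/matrix/data frame).
#' @param tau True change-point indices.
#' @param method Scoring method, as in [cpd()].
#' @param grids Named list with any of `h`, `r_hat`, `alpha`, `k`;
#'   defaults from [default_grids()].
#' @param M Margin in points.
#' @param stride Evaluation step.
#' @param r1,r2 Window column counts; `NULL` for the `max(2, floor(h/2))`
#'   default.
#' @param K,k_map Diffusion-map neighbour parameters.
#' @param normalize Range-normalise first?
#' @param min_sep,threshold_mult Detection rule for the reported F1/RI.
#' @return A list of class `"cpd_grid_search"` with `best_params`,
#'   `best_auc`, `result` (a `"cpd_eval"`), `scores` (the winning score
#'   series as a [cpd()]-like object) and `table` (AUC of every combination).
#' @export
grid_search_best_auc <- function(x, tau,
                                 method = c("cpd_dm", "sst", "hotelling_t2", "knn"),
                                 grids = list(), M = 20L, stride = 1L,
                                 r1 = NULL, r2 = NULL, K = 7L, k_map = 7L,
                                 normalize = TRUE, min_sep = M,
                                 threshold_mult = 1) {
  method <- match.arg(method)
  g <- utils::modifyList(default_grids(), grids)
  if (!length(g$h)) stop("empty `h` grid")
  X <- as_series_matrix(x)
  if (normalize) X <- range_normalize(X)
  best <- NULL
  rows <- list()
  for (h in sort(as.integer(g$h))) {
    cfg <- window_config(h = h, r1 = r1, r2 = r2, lag = h %/% 4L,
                         stride = stride)
    scan <- switch(method,
      cpd_dm = scan_cpd_dm(X, cfg, g$r_hat, g$alpha, K = K, k_map = k_map),
      sst = scan_sst(X, cfg, g$r_hat),
      hotelling_t2 = scan_hotelling_t2(X, cfg),
      knn = scan_knn(X, cfg, g$k))
    if (!length(scan$t_eval)) next
    lab <- margin_labels(scan$t_eval, tau, M)
    for (ci in seq_len(max(1L, nrow(scan$combos)))) {
      s <- scan$scores[, ci]
      auc <- tryCatch(auc_rank(s, lab), error = function(e) NA_real_)
      prm <- c(list(h = h),
               if (ncol(scan$combos)) as.list(scan$combos[ci, , drop = FALSE]))
      rows[[length(rows) + 1L]] <-
        data.frame(h = h,
                   r_hat = if (!is.null(prm$r_hat)) prm$r_hat else NA_integer_,
                   alpha = if (!is.null(prm$alpha)) prm$alpha else NA_real_,
                   k = if (!is.null(prm$k)) prm$k else NA_integer_,
                   auc = auc)
      if (is.finite(auc) && (is.null(best) || auc > best$auc)) {
        best <- list(auc = auc, params = prm, cfg = cfg,
                     t_eval = scan$t_eval, s = s)
      }
    }
  }
  if (is.null(best)) stop("grid search produced no defined AUC")
  fit <- structure(list(
    scores = { z <- rep(NA_real_, nrow(X)); z[best$t_eval] <- best$s; z },
    t_eval = best$t_eval, valid_range = valid_time_range(nrow(X), best$cfg),
    method = method, params = best$params[setdiff(names(best$params), "h")],
    config = best$cfg, series = X, N = nrow(X), m = ncol(X),
    normalized = normalize, call = match.call()), class = "cpd")
  res <- evaluate_scores(fit, tau, M = M, min_sep = min_sep,
                         threshold_mult = threshold_mult)
  structure(list(best_params = best$params, best_auc = best$auc,
                 result = res, scores = fit, table = do.call(rbind, rows)),
            class = "cpd_grid_search")
}

#' @export
print.cpd_grid_search <- function(x, ...) {
  p <- x$best_params
  cat("grid search best configuration:",
      paste(names(p), unlist(p), sep = " = ", collapse = ", "), "\n")
  print(x$result)
  invisible(x)
}
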