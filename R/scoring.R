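#' Change score between two embedded windows
#'
#' The Frobenius norm of the element-wise difference between the embedded
#' past and current windows; rows are matched in time order within each
#' window, which requires equal shapes (`r1 == r2` and a common `r_hat`).
#'
#' @param P_emb,Q_emb Embedded coordinates: matrices of identical shape, or
#'   `"diffusion_embedding"` objects.
#' @return A non-negative number.
#' @export
change_score <- function(P_emb, Q_emb) {
  if (inherits(P_emb, "diffusion_embedding")) P_emb <- P_emb$coords
  if (inherits(Q_emb, "diffusion_embedding")) Q_emb <- Q_emb$coords
  P_emb <- as.matrix(P_emb); Q_emb <- as.matrix(Q_emb)
  if (!identical(dim(P_emb), dim(Q_emb)))
    stop("embedded windows have different shapes; CPD-DM requires r1 == r2 ",
         "and a common r_hat")
  sqrt(sum((P_emb - Q_emb)^2))
}

# ---- per-method scanners -------------------------------------------------
# Each scanner returns list(t_eval, scores) where `scores` is a matrix with
# one row per evaluated time and one column per hyperparameter combination
# (data.frame `combos` describes the columns). A failure at one time point
# yields NA in that row, never an abort.

scan_cpd_dm <- function(X, cfg, r_hat_grid, alpha_grid, K = 7L, k_map = 7L,
                        kernel_two_factor = TRUE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  X <- as_series_matrix(X)
  if (cfg$r1 != cfg$r2)
    stop("CPD-DM requires r1 == r2 (embedded windows are differenced row-for-row)")
  r <- cfg$r1 * ncol(X)
  r_hat_grid <- sort(unique(as.integer(r_hat_grid)))
  alpha_grid <- sort(unique(as.numeric(alpha_grid)))
  if (any(r_hat_grid < 1L) || any(r_hat_grid > r - 1L))
    stop(sprintf("`r_hat` must lie in [1, %d] for r1 * m = %d window columns",
                 r - 1L, r))
  rmax <- max(r_hat_grid)
  K_eff <- min(as.integer(K), r - 1L)
  k_map <- min(as.integer(k_map), r)
  rng <- valid_time_range(nrow(X), cfg)
  t_eval <- if (rng[1] > rng[2]) integer(0) else seq.int(rng[1], rng[2], by = cfg$stride)
  combos <- expand.grid(alpha = alpha_grid, r_hat = r_hat_grid,
                        KEEP.OUT.ATTRS = FALSE)[, c("r_hat", "alpha")]
  if (engine == "cpp") {
    scores <- .cpp_scan_cpd_dm(X, as.integer(t_eval), cfg$h, cfg$r1, cfg$lag,
                               as.integer(combos$r_hat),
                               as.numeric(combos$alpha), K_eff, k_map,
                               isTRUE(kernel_two_factor))
    scores[!is.finite(scores)] <- NA_real_
    return(list(t_eval = t_eval, scores = scores, combos = combos))
  }
  scores <- matrix(NA_real_, length(t_eval), nrow(combos))
  nidx <- seq.int(2L, 1L + rmax)      # non-trivial eigenpairs
  KKT <- matrix(0, k_map + 1L, k_map + 1L)
  KKT[k_map + 1L, seq_len(k_map)] <- 1
  KKT[seq_len(k_map), k_map + 1L] <- 1
  rh_seq <- seq_len(k_map)
  for (ti in seq_along(t_eval)) {
    s_t <- tryCatch({
      pair <- build_multichannel_pair(X, t_eval[ti], cfg)
      P <- pair$P; Q <- pair$Q
      # self-tuning affinity graph over P's columns
      G <- crossprod(P)
      np <- diag(G)
      d2P <- pmax(outer(np, np, `+`) - 2 * G, 0)
      sigma <- pmax(vapply(seq_len(r), function(i)
        sqrt(sort(d2P[i, -i], partial = K_eff)[K_eff]), numeric(1)), 1e-12)
      denom <- outer(sigma, sigma)
      if (kernel_two_factor) denom <- 2 * denom
      W <- exp(-d2P / denom)
      W <- (W + t(W)) / 2
      diag(W) <- 1
      # spectrum via the symmetric conjugate
      b <- rowSums(W)
      isq <- 1 / sqrt(b)
      A <- W * tcrossprod(isq)
      e <- eigen(A, symmetric = TRUE)
      ord <- order(abs(e$values), decreasing = TRUE)
      lam <- e$values[ord][nidx]
      phi <- (e$vectors[, ord[nidx], drop = FALSE] * isq) * sqrt(sum(b))
      # out-of-sample affine k-NN weights, reusing the cross-products
      CQP <- crossprod(Q, P)
      d2Q <- pmax(outer(colSums(Q^2), np, `+`) - 2 * CQP, 0)
      Qphi <- matrix(0, r, rmax)
      for (i in seq_len(r)) {
        di <- d2Q[i, ]
        jmin <- which.min(di)
        if (di[jmin] < 1e-24) {
          Qphi[i, ] <- phi[jmin, ]
          next
        }
        nb <- order(di)[seq_len(k_map)]
        KKT[rh_seq, rh_seq] <- 2 * G[nb, nb]
        rhs <- c(2 * CQP[i, nb], 1)
        w <- tryCatch(solve(KKT, rhs)[rh_seq], error = function(e) NULL)
        if (is.null(w) || any(!is.finite(w))) w <- rep(1 / k_map, k_map)
        Qphi[i, ] <- w %*% phi[nb, , drop = FALSE]
      }
      base2 <- colSums((phi - Qphi)^2)
      vapply(seq_len(nrow(combos)), function(ci) {
        la <- power_eigenvalues(lam, combos$alpha[ci])$lam_a
        sqrt(sum(base2[seq_len(combos$r_hat[ci])] *
                   la[seq_len(combos$r_hat[ci])]^2))
      }, numeric(1))
    }, error = function(e) rep(NA_real_, nrow(combos)))
    scores[ti, ] <- s_t
  }
  list(t_eval = t_eval, scores = scores, combos = combos)
}

scan_sst <- function(X, cfg, r_hat_grid) {
  X <- as_series_matrix(X)
  m <- ncol(X)
  r_hat_grid <- sort(unique(as.integer(r_hat_grid)))
  rmax <- max(r_hat_grid)
  if (any(r_hat_grid < 1L) || rmax > min(cfg$h, cfg$r1 * m, cfg$r2 * m))
    stop(sprintf("`r_hat` must lie in [1, %d]",
                 min(cfg$h, cfg$r1 * m, cfg$r2 * m)))
  rng <- valid_time_range(nrow(X), cfg)
  t_eval <- if (rng[1] > rng[2]) integer(0) else seq.int(rng[1], rng[2], by = cfg$stride)
  combos <- data.frame(r_hat = r_hat_grid)
  scores <- matrix(NA_real_, length(t_eval), nrow(combos))
  for (ti in seq_along(t_eval)) {
    s_t <- tryCatch({
      pair <- build_multichannel_pair(X, t_eval[ti], cfg)
      U <- svd(pair$P, nu = rmax, nv = 0)$u
      Z <- svd(pair$Q, nu = rmax, nv = 0)$u
      C <- crossprod(U, Z)
      vapply(r_hat_grid, function(rh) {
        smax <- svd(C[seq_len(rh), seq_len(rh), drop = FALSE], nu = 0, nv = 0)$d[1]
        min(max(1 - min(smax, 1)^2, 0), 1)
      }, numeric(1))
    }, error = function(e) rep(NA_real_, nrow(combos)))
    scores[ti, ] <- s_t
  }
  list(t_eval = t_eval, scores = scores, combos = combos)
}

scan_hotelling_t2 <- function(X, cfg) {
  X <- as_series_matrix(X)
  rng <- valid_time_range(nrow(X), cfg)
  t_eval <- if (rng[1] > rng[2]) integer(0) else seq.int(rng[1], rng[2], by = cfg$stride)
  scores <- matrix(NA_real_, length(t_eval), 1L)
  for (ti in seq_along(t_eval)) {
    scores[ti, 1L] <- tryCatch({
      pair <- build_multichannel_pair(X, t_eval[ti], cfg)
      delta <- rowMeans(pair$Q) - rowMeans(pair$P)
      S_P <- stats::cov(t(pair$P))
      gamma <- max(1e-6 * sum(diag(S_P)) / cfg$h, 1e-12)
      drop(crossprod(delta, solve(S_P + gamma * diag(cfg$h), delta)))
    }, error = function(e) NA_real_)
  }
  list(t_eval = t_eval, scores = scores, combos = data.frame(dummy = 1)[, 0])
}

scan_knn <- function(X, cfg, k_grid) {
  X <- as_series_matrix(X)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L) || max(k_grid) > cfg$r1 * ncol(X))
    stop(sprintf("`k` must lie in [1, %d]", cfg$r1 * ncol(X)))
  kmax <- max(k_grid)
  rng <- valid_time_range(nrow(X), cfg)
  t_eval <- if (rng[1] > rng[2]) integer(0) else seq.int(rng[1], rng[2], by = cfg$stride)
  combos <- data.frame(k = k_grid)
  scores <- matrix(NA_real_, length(t_eval), nrow(combos))
  for (ti in seq_along(t_eval)) {
    s_t <- tryCatch({
      pair <- build_multichannel_pair(X, t_eval[ti], cfg)
      D <- pairwise_dist(pair$Q, pair$P)      # rows: Q columns
      rmeans <- .cpp_knn_running_means(D, kmax)
      vapply(k_grid, function(k) mean(rmeans[k, ]), numeric(1))
    }, error = function(e) rep(NA_real_, nrow(combos)))
    scores[ti, ] <- s_t
  }
  list(t_eval = t_eval, scores = scores, combos = combos)
}

#' Turn a change-score series into discrete detected change points
#'
#' Candidate points are strict local maxima of the defined scores (on the
#' evaluated time grid) that exceed `mean + threshold_mult * SD` of the
#' defined scores. Candidates are kept greedily in descending score order
#' subject to pairwise gaps of at least `min_sep` points.
#'
#' @param scores A fitted [cpd()] object, or a numeric score vector.
#' @param t Evaluation time indices matching `scores` when a numeric vector
#'   is given; ignored for `cpd` objects.
#' @param min_sep Minimum separation between detected points, in time
#'   points. A natural default is the evaluation margin `M`.
#' @param threshold_mult Multiplier on the score SD above the mean.
#' @return Sorted integer vector of detected change-point times (1-based),
#'   with the detection rule in `attr(, "rule")`.
#' @export
detect_change_points <- function(scores, t = NULL, min_sep = 20L,
                                 threshold_mult = 1) {
  if (inherits(scores, "cpd")) {
    t <- scores$t_eval
    s <- scores$scores[t]
  } else {
    s <- as.numeric(scores)
    if (is.null(t)) t <- seq_along(s)
    if (length(t) != length(s)) stop("`t` must match `scores` in length")
  }
  min_sep <- as.integer(min_sep)
  if (is.na(min_sep) || min_sep < 1L) stop("`min_sep` must be an integer >= 1")
  keep <- is.finite(s)
  s <- s[keep]; t <- t[keep]
  rule <- list(threshold_mult = threshold_mult, min_sep = min_sep)
  if (length(s) == 0L)
    return(structure(integer(0), rule = rule))
  thr <- mean(s) + threshold_mult * (if (length(s) > 1L) stats::sd(s) else 0)
  n <- length(s)
  is_max <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1L || s[i] > s[i - 1L]
    right_ok <- i == n || s[i] >= s[i + 1L]
    left_ok && right_ok
  }, logical(1))
  cand <- which(is_max & s > thr)
  if (length(cand) == 0L)
    return(structure(integer(0), rule = rule))
  cand <- cand[order(-s[cand], t[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(t[i] - kept) >= min_sep)) kept <- c(kept, t[i])
  }
  structure(sort(as.integer(kept)), rule = rule)
}
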