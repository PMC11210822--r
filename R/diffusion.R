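# Pairwise Euclidean distances between the columns of P (points in R^h).
pairwise_dist <- function(P, Q = NULL) {
  G <- if (is.null(Q)) crossprod(P) else crossprod(P, Q)
  np <- colSums(P^2)
  nq <- if (is.null(Q)) np else colSums(Q^2)
  d2 <- outer(np, nq, `+`) - 2 * G
  sqrt(pmax(d2, 0))
}

#' Self-tuning local scale parameters
#'
#' For each point (column), the local scale is its Euclidean distance to its
#' `K`-th nearest neighbour, self excluded — the self-tuning bandwidth rule
#' of Zelnik-Manor and Perona, with `K = 7` as the recommended default.
#' Scales are floored at `1e-12` so duplicated points cannot produce a zero
#' bandwidth.
#'
#' @param points Matrix whose columns are the points (`h x r`).
#' @param K Neighbour rank (`>= 1`); clamped to `r - 1` with a warning.
#' @return Numeric vector of `r` positive scales.
#' @export
local_scales <- function(points, K = 7L) {
  points <- as.matrix(points)
  r <- ncol(points)
  if (r < 2L) stop("need at least 2 points to compute local scales")
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("`K` must be an integer >= 1")
  if (K > r - 1L) {
    warning(sprintf("K = %d exceeds r - 1 = %d; clamped", K, r - 1L))
    K <- r - 1L
  }
  d <- pairwise_dist(points)
  sigma <- vapply(seq_len(r), function(i) {
    di <- d[i, -i]
    sort(di, partial = K)[K]
  }, numeric(1))
  pmax(sigma, 1e-12)
}

#' Self-tuning Gaussian affinity graph
#'
#' Edge weights `w_ij = exp(-||p_i - p_j||^2 / (2 sigma_i sigma_j))`
#' (symmetric, unit diagonal, entries in (0, 1]). `kernel_two_factor = FALSE`
#' drops the factor 2 in the denominator, matching the original self-tuning
#' kernel.
#'
#' @inheritParams local_scales
#' @param sigma Positive local scales, typically from [local_scales()].
#' @param kernel_two_factor Keep the factor 2 in the kernel denominator?
#' @return A list of class `"affinity_graph"` with the weight matrix `W`,
#'   `sigma` and the flag used.
#' @export
affinity <- function(points, sigma, kernel_two_factor = TRUE) {
  points <- as.matrix(points)
  r <- ncol(points)
  if (length(sigma) != r || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be a positive vector with one entry per point")
  d <- pairwise_dist(points)
  denom <- outer(sigma, sigma)
  if (kernel_two_factor) denom <- 2 * denom
  W <- exp(-(d^2) / denom)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  structure(list(W = W, sigma = sigma, kernel_two_factor = kernel_two_factor),
            class = "affinity_graph")
}

#' Row-normalise an affinity matrix into a Markov matrix
#'
#' @param W Symmetric affinity matrix, or an `"affinity_graph"`.
#' @return Row-stochastic matrix `D1` with `d_ij = w_ij / sum_k w_ik`.
#' @export
markov_normalize <- function(W) {
  if (inherits(W, "affinity_graph")) W <- W$W
  rs <- rowSums(W)
  if (any(rs <= 0)) stop("every row of W must have positive sum")
  W / rs
}

#' Diffusion operator (Markov matrix spectrum at diffusion time alpha)
#'
#' Builds the row-stochastic operator `D1` from a symmetric affinity `W` and
#' decomposes it through the symmetric conjugate
#' `A = S^{-1/2} W S^{-1/2}` (with `S = diag(rowSums(W))`), which guarantees
#' a real spectrum and stable fractional powers. Right eigenvectors `phi`
#' are scaled so that `sum_k psi0_k phi(k)^2 = 1`, making the trivial
#' eigenvector exactly constant 1 and the diffusion-distance/embedding
#' identity hold in the reciprocal weight mode.
#'
#' Eigenpairs are sorted by `|lambda|` descending. For non-integer `alpha`,
#' negative eigenvalues are clipped to 0 before raising to the power (the
#' number clipped is recorded in `n_clipped`), so coordinates stay real.
#'
#' @param W Symmetric affinity matrix or `"affinity_graph"`.
#' @param alpha Diffusion time (`> 0`), possibly fractional.
#' @return An object of class `"diffusion_operator"` with elements `D1`,
#'   `alpha`, `eigenvalues`, `eigenvalues_alpha`, `eigenvectors` (right,
#'   `phi`), `left` (`xi`, biorthogonal left vectors), `degrees` (`b`),
#'   `psi0` and `n_clipped`.
#' @export
diffusion_operator <- function(W, alpha = 1) {
  if (inherits(W, "affinity_graph")) W <- W$W
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("`alpha` must be a single positive number")
  r <- nrow(W)
  b <- rowSums(W)
  if (any(b <= 0)) stop("every row of W must have positive sum")
  isq <- 1 / sqrt(b)
  A <- W * tcrossprod(isq)
  e <- eigen(A, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  lam <- e$values[ord]
  V <- e$vectors[, ord, drop = FALSE]
  sb <- sqrt(sum(b))
  phi <- (V * isq) * sb          # right eigenvectors, psi0-weighted unit norm
  xi <- (V * sqrt(b)) / sb       # left eigenvectors, biorthogonal to phi
  # fix each eigenvector's sign (largest-magnitude entry positive); flip the
  # left vectors with them so biorthogonality and reconstruction survive
  sgn <- apply(phi, 2L, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  phi <- sweep(phi, 2L, sgn, `*`)
  xi <- sweep(xi, 2L, sgn, `*`)
  pw <- power_eigenvalues(lam, alpha)
  structure(list(D1 = W / b, alpha = alpha,
                 eigenvalues = lam, eigenvalues_alpha = pw$lam_a,
                 eigenvectors = phi, left = xi,
                 degrees = b, psi0 = b / sum(b), n_clipped = pw$n_clipped),
            class = "diffusion_operator")
}

power_eigenvalues <- function(lam, alpha) {
  if (alpha == round(alpha)) {
    list(lam_a = lam^alpha, n_clipped = 0L)
  } else {
    neg <- lam < 0
    lam_a <- ifelse(neg, 0, lam^alpha)
    list(lam_a = lam_a, n_clipped = sum(neg))
  }
}

#' Re-power a diffusion operator to a new diffusion time
#'
#' Replaces `alpha` without recomputing the spectrum: the operator at time
#' `alpha` has eigenvalues `lambda^alpha` with unchanged eigenvectors. For
#' integer `alpha` the reconstructed matrix equals the repeated matrix
#' product of `D1`.
#'
#' @param op A `"diffusion_operator"`.
#' @param alpha New diffusion time (`> 0`).
#' @return The operator with updated `alpha` and `eigenvalues_alpha`.
#' @export
diffusion_power <- function(op, alpha) {
  stopifnot(inherits(op, "diffusion_operator"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("`alpha` must be a single positive number")
  pw <- power_eigenvalues(op$eigenvalues, alpha)
  op$alpha <- alpha
  op$eigenvalues_alpha <- pw$lam_a
  op$n_clipped <- pw$n_clipped
  op
}

#' Reconstruct the transition matrix at the operator's diffusion time
#'
#' @param op A `"diffusion_operator"`.
#' @return The `r x r` matrix `D^(alpha)` (row-stochastic).
#' @export
transition_matrix <- function(op) {
  stopifnot(inherits(op, "diffusion_operator"))
  op$eigenvectors %*% (op$eigenvalues_alpha * t(op$left))
}

#' @export
print.diffusion_operator <- function(x, ...) {
  cat(sprintf("diffusion_operator: %d points, alpha = %g\n",
              nrow(x$D1), x$alpha))
  cat("  leading |eigenvalues|:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  if (x$n_clipped > 0)
    cat(sprintf("  %d negative eigenvalue(s) clipped for fractional alpha\n",
                x$n_clipped))
  invisible(x)
}

#' Diffusion-map embedding
#'
#' Coordinates are the eigenvalue-scaled right eigenvectors
#' `lambda_j^alpha * phi_j` for the leading `r_hat` non-trivial eigenpairs
#' (the trivial pair `lambda = 1`, constant eigenvector is dropped by
#' default). Each eigenvector's sign is fixed so its largest-magnitude entry
#' is positive.
#'
#' @param op A `"diffusion_operator"`.
#' @param r_hat Embedded dimension, `1 <= r_hat <= r - 1`.
#' @param drop_trivial Drop the trivial constant eigenpair? (default TRUE)
#' @return An object of class `"diffusion_embedding"`: `coords`
#'   (`r x r_hat`, row i = embedded point i), `r_hat`, `eigenvalues_used`
#'   (already raised to `alpha`), `alpha`.
#' @export
diffusion_embed <- function(op, r_hat, drop_trivial = TRUE) {
  stopifnot(inherits(op, "diffusion_operator"))
  r <- nrow(op$D1)
  r_hat <- as.integer(r_hat)
  rmax <- if (drop_trivial) r - 1L else r
  if (is.na(r_hat) || r_hat < 1L || r_hat > rmax)
    stop(sprintf("`r_hat` must be in [1, %d]", rmax))
  idx <- if (drop_trivial) seq.int(2L, 1L + r_hat) else seq_len(r_hat)
  phi <- op$eigenvectors[, idx, drop = FALSE]
  sgn <- apply(phi, 2L, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  phi <- sweep(phi, 2L, sgn, `*`)
  lam_a <- op$eigenvalues_alpha[idx]
  structure(list(coords = sweep(phi, 2L, lam_a, `*`),
                 r_hat = r_hat, eigenvalues_used = lam_a, alpha = op$alpha),
            class = "diffusion_embedding")
}

#' Diffusion distance between two points of the operator
#'
#' `sqrt( sum_k (d_ik^(alpha) - d_jk^(alpha))^2 * w_k )` over the rows of the
#' `alpha`-step transition matrix. In `"as_written"` mode the weight is the
#' stationary weight `w_k = psi0_k`; in `"reciprocal"` mode it is
#' `1 / psi0_k`, the classical definition under which the distance equals
#' the Euclidean distance between full embedding rows.
#'
#' @param op A `"diffusion_operator"`.
#' @param i,j Point indices.
#' @param weight_mode `"as_written"` or `"reciprocal"`.
#' @return A non-negative number.
#' @export
diffusion_distance <- function(op, i, j,
                               weight_mode = c("as_written", "reciprocal")) {
  stopifnot(inherits(op, "diffusion_operator"))
  weight_mode <- match.arg(weight_mode)
  r <- nrow(op$D1)
  i <- as.integer(i); j <- as.integer(j)
  if (anyNA(c(i, j)) || i < 1L || i > r || j < 1L || j > r)
    stop(sprintf("indices must lie in [1, %d]", r))
  row_of <- function(k)
    drop((op$eigenvectors[k, ] * op$eigenvalues_alpha) %*% t(op$left))
  dd <- row_of(i) - row_of(j)
  w <- if (weight_mode == "as_written") op$psi0 else 1 / op$psi0
  sqrt(sum(dd^2 * w))
}

# Affine k-NN weights mapping each column of Q_points onto columns of
# P_points: rows sum to 1; an exact duplicate gets a unit weight on its
# match; degenerate neighbour geometry falls back to uniform weights.
oos_weights <- function(Q_points, P_points, k_map) {
  Q_points <- as.matrix(Q_points); P_points <- as.matrix(P_points)
  rP <- ncol(P_points); rQ <- ncol(Q_points)
  k_map <- as.integer(k_map)
  if (is.na(k_map) || k_map < 1L || k_map > rP)
    stop(sprintf("`k_map` must be in [1, %d]", rP))
  D <- pairwise_dist(Q_points, P_points)  # rQ x rP
  Wt <- matrix(0, rQ, rP)
  for (i in seq_len(rQ)) {
    di <- D[i, ]
    jmin <- which.min(di)                 # ties: lowest index
    if (di[jmin] < 1e-12) {
      Wt[i, jmin] <- 1
      next
    }
    nb <- order(di)[seq_len(k_map)]
    A <- P_points[, nb, drop = FALSE]
    M <- crossprod(A)
    KKT <- rbind(cbind(2 * M, 1), c(rep(1, k_map), 0))
    rhs <- c(2 * crossprod(A, Q_points[, i]), 1)
    w <- tryCatch(solve(KKT, rhs)[seq_len(k_map)], error = function(e) NULL)
    if (is.null(w) || any(!is.finite(w))) w <- rep(1 / k_map, k_map)
    Wt[i, nb] <- w
  }
  Wt
}

#' Out-of-sample extension of a diffusion embedding
#'
#' Maps new points into an existing embedding without recomputing the
#' spectrum: each new point is written as an affine (weights summing to 1)
#' least-squares combination of its `k_map` nearest reference columns in the
#' original space, and the same weights are applied to the neighbours'
#' embedded rows. An exact duplicate of a reference point maps to that
#' point's embedded row; degenerate neighbour geometry falls back to uniform
#' weights rather than aborting.
#'
#' @param Q_points New points (columns, `h x r2`).
#' @param P_points Reference points the embedding was built from
#'   (`h x r1` columns).
#' @param embedding A `"diffusion_embedding"` built from `P_points`.
#' @param k_map Number of neighbours for the affine map (default 7).
#' @return `r2 x r_hat` matrix of embedded coordinates for `Q_points`.
#' @export
out_of_sample_extend <- function(Q_points, P_points, embedding, k_map = 7L) {
  stopifnot(inherits(embedding, "diffusion_embedding"))
  if (ncol(as.matrix(P_points)) != nrow(embedding$coords))
    stop("`P_points` must have one column per embedded row")
  Wt <- oos_weights(Q_points, P_points, k_map)
  Wt %*% embedding$coords
}
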