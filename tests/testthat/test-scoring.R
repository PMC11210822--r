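test_that("change score is the Frobenius norm of the embedded difference", {
  A <- matrix(rnorm(12), 4, 3)
  expect_equal(change_score(A, A), 0)
  expect_equal(change_score(A, A + 0.5), 0.5 * sqrt(12))
  expect_equal(change_score(3 * A, 3 * (A + 0.5)), 3 * change_score(A, A + 0.5))
  expect_error(change_score(A, matrix(0, 4, 2)), "r1 == r2")
})

test_that("the C++ scan agrees with the R reference scanner", {
  set.seed(31)
  X <- matrix(rnorm(1200), 400, 3)
  cfg <- cpdm:::window_config(h = 16, r1 = 6, lag = 4, stride = 7)
  a <- cpdm:::scan_cpd_dm(X, cfg, c(2, 5), c(0.5, 1, 3), engine = "cpp")
  b <- cpdm:::scan_cpd_dm(X, cfg, c(2, 5), c(0.5, 1, 3), engine = "r")
  expect_identical(a$t_eval, b$t_eval)
  expect_identical(a$combos, b$combos)
  expect_equal(a$scores, b$scores, tolerance = 1e-10)
})

test_that("the scanner composes the exported diffusion operations", {
  set.seed(32)
  X <- matrix(rnorm(600), 300, 2)
  cfg <- cpdm:::window_config(h = 12, r1 = 8, lag = 3, stride = 1)
  sc <- cpdm:::scan_cpd_dm(X, cfg, 3, 0.5)
  t0 <- sc$t_eval[40]
  pair <- build_multichannel_pair(X, t0, cfg)
  op <- diffusion_operator(affinity(pair$P, local_scales(pair$P, 7)),
                           alpha = 0.5)
  emb <- diffusion_embed(op, 3)
  q_emb <- out_of_sample_extend(pair$Q, pair$P, emb, k_map = 7)
  expect_equal(sc$scores[40, 1], change_score(emb$coords, q_emb),
               tolerance = 1e-8)
})

test_that("constant series give (near-)zero CPD-DM scores", {
  fit <- cpd(matrix(3, 200, 2), method = "cpd_dm", h = 10, lag = 2,
             r_hat = 2)
  expect_true(all(fit$scores[fit$t_eval] <= 1e-6))
})

test_that("a clean step is localised by every method within h + lag", {
  sf <- step_fixture(N = 200, tau = 100, amplitude = 5)
  x <- sf$series[[1]]
  for (m in c("cpd_dm", "sst", "hotelling_t2", "knn")) {
    fit <- cpd(x, method = m, h = 20, lag = 5, r_hat = 2, k = 2)
    expect_lte(abs(which.max(fit$scores) - 100), 25, # h + lag
               label = sprintf("argmax offset for %s", m))
  }
})

test_that("score series are deterministic across runs", {
  set.seed(33)
  X <- matrix(rnorm(900), 300, 3)
  f1 <- cpd(X, "cpd_dm", h = 16, lag = 4, r_hat = 3, alpha = 0.5)
  f2 <- cpd(X, "cpd_dm", h = 16, lag = 4, r_hat = 3, alpha = 0.5)
  expect_identical(f1$scores, f2$scores)
})

test_that("too-short series yield an empty valid range, not an error", {
  fit <- cpd(rnorm(15), "cpd_dm", h = 10, r1 = 8, r2 = 8, lag = 2, r_hat = 2)
  expect_length(fit$t_eval, 0)
  expect_true(all(is.na(fit$scores)))
})

test_that("SST score matches the principal-angle closed form", {
  set.seed(34)
  X <- matrix(rnorm(800), 400, 2)
  cfg <- cpdm:::window_config(h = 10, r1 = 6, lag = 5, stride = 3)
  sc <- cpdm:::scan_sst(X, cfg, c(1, 3))
  # oracle: svd computed directly in the test
  for (ti in c(10, 30)) {
    pair <- build_multichannel_pair(X, sc$t_eval[ti], cfg)
    for (ci in 1:2) {
      rh <- sc$combos$r_hat[ci]
      U <- svd(pair$P)$u[, seq_len(rh), drop = FALSE]
      Z <- svd(pair$Q)$u[, seq_len(rh), drop = FALSE]
      expect_equal(sc$scores[ti, ci],
                   1 - max(svd(crossprod(U, Z))$d)^2, tolerance = 1e-8)
    }
  }
  expect_true(all(sc$scores >= 0 & sc$scores <= 1))
  # identical windows -> zero score
  f0 <- cpd(X, "sst", h = 10, r1 = 6, r2 = 6, lag = 0, r_hat = 3)
  expect_true(all(f0$scores[f0$t_eval] <= 1e-6))
})

test_that("Hotelling T2 matches its quadratic-form definition", {
  set.seed(35)
  X <- matrix(rnorm(600), 300, 2)
  cfg <- cpdm:::window_config(h = 8, r1 = 10, lag = 4, stride = 5)
  sc <- cpdm:::scan_hotelling_t2(X, cfg)
  for (ti in c(5, 20)) {
    pair <- build_multichannel_pair(X, sc$t_eval[ti], cfg)
    d <- rowMeans(pair$Q) - rowMeans(pair$P)
    S <- cov(t(pair$P))
    g <- max(1e-6 * sum(diag(S)) / 8, 1e-12)
    expect_equal(sc$scores[ti, 1],
                 drop(crossprod(d, solve(S + g * diag(8), d))),
                 tolerance = 1e-8)
  }
  # Q = P -> 0; constant windows stay finite thanks to the ridge
  f0 <- cpd(X, "hotelling_t2", h = 8, r1 = 10, r2 = 10, lag = 0)
  expect_true(all(abs(f0$scores[f0$t_eval]) <= 1e-6))
  fc <- cpd(matrix(1, 100, 1), "hotelling_t2", h = 8, r1 = 10, r2 = 10,
            lag = 2, normalize = FALSE)
  expect_true(all(is.finite(fc$scores[fc$t_eval])))
})

test_that("KNN score matches a direct nearest-neighbour oracle", {
  set.seed(36)
  X <- matrix(rnorm(500), 250, 2)
  cfg <- cpdm:::window_config(h = 6, r1 = 8, lag = 3, stride = 4)
  sc <- cpdm:::scan_knn(X, cfg, c(1, 4))
  for (ti in c(3, 17)) {
    pair <- build_multichannel_pair(X, sc$t_eval[ti], cfg)
    for (ci in 1:2) {
      k <- sc$combos$k[ci]
      per_q <- apply(pair$Q, 2, function(q) {
        d <- sort(sqrt(colSums((pair$P - q)^2)))
        mean(d[seq_len(k)])
      })
      expect_equal(sc$scores[ti, ci], mean(per_q), tolerance = 1e-6)
    }
  }
  # every Q column present in P (lag 0) with k = 1 -> zero
  f0 <- cpd(X, "knn", h = 6, r1 = 8, r2 = 8, lag = 0, k = 1)
  expect_true(all(f0$scores[f0$t_eval] <= 1e-6))
})

test_that("detection keeps isolated peaks and suppresses close rivals", {
  flat <- rep(1, 50)
  expect_length(detect_change_points(flat, min_sep = 5), 0)
  peak <- c(rep(0, 20), 0.2, 1, 0.3, rep(0, 27))
  expect_equal(as.integer(detect_change_points(peak, min_sep = 5)), 22L)
  two <- rep(0, 40); two[c(20, 23)] <- c(0.8, 1)
  got <- detect_change_points(two, min_sep = 10)
  expect_equal(as.integer(got), 23L)
  # min separation respected for well-separated peaks
  three <- rep(0, 60); three[c(10, 30, 50)] <- c(0.9, 1, 0.8)
  expect_equal(as.integer(detect_change_points(three, min_sep = 10)),
               c(10L, 30L, 50L))
})
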