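test_that("local scales equal the K-th nearest-neighbour distance", {
  pts <- rbind(seq(0, 2, by = 0.5))  # collinear, gap 0.5
  expect_equal(local_scales(pts, K = 1), rep(0.5, 5))
  # duplicated points are floored, not zero
  dup <- cbind(c(1, 1), c(1, 1), c(2, 2))
  s <- local_scales(dup, K = 1)
  expect_true(all(s > 0))
  expect_equal(s[1], 1e-12)
  expect_warning(local_scales(dup, K = 10), "clamped")
  expect_error(local_scales(cbind(c(1, 1)), K = 1), "2 points")
})

test_that("affinity is a symmetric unit-diagonal kernel with the stated value", {
  pts <- random_points(4, 8, seed = 21)
  sig <- local_scales(pts, K = 3)
  W <- affinity(pts, sig)$W
  expect_equal(W, t(W))
  expect_equal(diag(W), rep(1, 8))
  expect_true(all(W > 0 & W <= 1))
  # distance^2 = 2 sigma_i sigma_j -> weight exp(-1)
  p2 <- cbind(c(0, 0), c(2, 0))
  W2 <- affinity(p2, sigma = c(sqrt(2), sqrt(2)))$W
  expect_equal(W2[1, 2], exp(-1))
  expect_error(affinity(p2, sigma = c(1, -1)), "positive")
})

test_that("markov normalisation gives row-stochastic matrices", {
  W <- rbind(c(1, 0.5), c(0.5, 1))
  expect_equal(markov_normalize(W), rbind(c(2/3, 1/3), c(1/3, 2/3)))
  W8 <- affinity(random_points(5, 8, 22), rep(1, 8))$W
  D1 <- markov_normalize(W8)
  expect_equal(rowSums(D1), rep(1, 8), tolerance = 1e-10)
})

test_that("the operator spectrum is real, bounded, with constant leading vector", {
  op <- random_operator(r = 12, seed = 23)
  expect_true(all(abs(op$eigenvalues) <= 1 + 1e-10))
  expect_equal(op$eigenvalues[1], 1)
  expect_equal(op$eigenvectors[, 1], rep(1, 12))  # psi0-normalised constant
  expect_equal(sum(op$psi0), 1)
  expect_equal(rowSums(op$D1), rep(1, 12), tolerance = 1e-10)
})

test_that("integer diffusion powers match repeated matrix multiplication", {
  pts <- random_points(4, 6, seed = 24)
  op <- diffusion_operator(affinity(pts, local_scales(pts, 2)), alpha = 1)
  D1 <- op$D1
  expect_equal(transition_matrix(op), D1, tolerance = 1e-10)
  op3 <- diffusion_power(op, 3)
  expect_equal(transition_matrix(op3), D1 %*% D1 %*% D1, tolerance = 1e-8)
  for (a in c(0.1, 0.5, 1, 10)) {
    Da <- transition_matrix(diffusion_power(op, a))
    expect_equal(rowSums(Da), rep(1, 6), tolerance = 1e-8)
  }
  expect_error(diffusion_power(op, 0), "positive")
})

test_that("diffusion distance matches the direct weighted row-difference sum", {
  op <- random_operator(r = 8, seed = 25, alpha = 0.7)
  Da <- transition_matrix(op)
  for (mode in c("as_written", "reciprocal")) {
    w <- if (mode == "as_written") op$psi0 else 1 / op$psi0
    for (pr in list(c(1, 5), c(2, 8), c(3, 3))) {
      brute <- sqrt(sum((Da[pr[1], ] - Da[pr[2], ])^2 * w))
      expect_equal(diffusion_distance(op, pr[1], pr[2], mode), brute,
                   tolerance = 1e-10)
    }
  }
  expect_equal(diffusion_distance(op, 4, 4), 0)
  expect_equal(diffusion_distance(op, 2, 6), diffusion_distance(op, 6, 2))
  expect_error(diffusion_distance(op, 0, 3), "indices")
})

test_that("embedding distances equal diffusion distances in reciprocal mode", {
  for (seed in 1:5) {
    op <- random_operator(r = 10, seed = seed, alpha = if (seed %% 2) 1 else 2)
    emb <- diffusion_embed(op, r_hat = 9)  # full non-trivial spectrum
    for (pr in list(c(1, 2), c(3, 9), c(5, 10))) {
      d_emb <- sqrt(sum((emb$coords[pr[1], ] - emb$coords[pr[2], ])^2))
      d_diff <- diffusion_distance(op, pr[1], pr[2], "reciprocal")
      expect_equal(d_emb, d_diff, tolerance = 1e-6)
    }
  }
})

test_that("embedding drops the trivial pair and separates two clusters", {
  set.seed(26)
  # moderate separation keeps the clusters coupled, so the leading
  # non-trivial eigenvector is the bipartition (a disconnected pair would
  # make the lambda = 1 eigenspace degenerate)
  pts <- cbind(matrix(rnorm(10, 0, 0.4), 2, 5),
               matrix(rnorm(10, 2, 0.4), 2, 5))
  op <- diffusion_operator(affinity(pts, local_scales(pts, 2)))
  emb <- diffusion_embed(op, r_hat = 1)
  expect_true(all(sign(emb$coords[1:5, 1]) == sign(emb$coords[1, 1])))
  expect_true(all(sign(emb$coords[6:10, 1]) == -sign(emb$coords[1, 1])))
  expect_error(diffusion_embed(op, r_hat = 10), "r_hat")
  # near-zero eigenvalues give near-zero coordinates
  emb9 <- diffusion_embed(op, r_hat = 9)
  tiny <- which(abs(emb9$eigenvalues_used) < 1e-8)
  if (length(tiny))
    expect_lt(max(abs(emb9$coords[, tiny])), 1e-6)
})

test_that("permuting input points permutes embedding rows", {
  pts <- random_points(4, 9, seed = 27)
  perm <- c(3, 1, 2, 7, 9, 8, 4, 6, 5)
  emb1 <- diffusion_embed(diffusion_operator(
    affinity(pts, local_scales(pts, 3))), r_hat = 3)
  emb2 <- diffusion_embed(diffusion_operator(
    affinity(pts[, perm], local_scales(pts[, perm], 3))), r_hat = 3)
  expect_equal(emb2$coords, emb1$coords[perm, ], tolerance = 1e-8)
})

test_that("out-of-sample extension reproduces duplicates, midpoints and self", {
  pts <- random_points(6, 9, seed = 28)
  # place points 1 and 2 close together and away from the rest, so the
  # midpoint's two nearest reference points are exactly p1 and p2
  pts[, 1] <- pts[, 1] + 10
  pts[, 2] <- pts[, 1] + 0.5
  op <- diffusion_operator(affinity(pts, local_scales(pts, 3)))
  emb <- diffusion_embed(op, r_hat = 4)
  # duplicate of p3 maps to embedded row 3
  q_dup <- pts[, 3, drop = FALSE]
  expect_equal(out_of_sample_extend(q_dup, pts, emb, k_map = 4)[1, ],
               emb$coords[3, ])
  # midpoint of p1, p2 with 2 neighbours -> average of rows 1, 2
  q_mid <- (pts[, 1] + pts[, 2]) / 2
  got <- out_of_sample_extend(cbind(q_mid), pts, emb, k_map = 2)[1, ]
  expect_equal(got, (emb$coords[1, ] + emb$coords[2, ]) / 2, tolerance = 1e-8)
  # self-extension identity
  expect_equal(out_of_sample_extend(pts, pts, emb, k_map = 5), emb$coords)
  expect_error(out_of_sample_extend(pts, pts, emb, k_map = 50), "k_map")
})

test_that("degenerate neighbour geometry falls back to uniform weights", {
  # all reference points identical except the query: KKT system is singular
  pts <- cbind(c(0, 0), c(0, 0), c(0, 0))
  emb <- structure(list(coords = rbind(1, 2, 3), r_hat = 1L,
                        eigenvalues_used = 1, alpha = 1),
                   class = "diffusion_embedding")
  got <- out_of_sample_extend(cbind(c(1, 1)), pts, emb, k_map = 3)
  expect_equal(got[1, 1], 2)  # uniform average of 1, 2, 3
})
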