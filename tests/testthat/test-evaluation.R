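test_that("true positive set uses the strict margin as printed", {
  expect_equal(true_positive_set(c(200, 400), 205, M = 20), 200)
  expect_length(true_positive_set(c(200, 400), integer(0), M = 20), 0)
  expect_equal(true_positive_set(c(200, 400), c(200, 400), M = 1),
               c(200, 400))
  # boundary: |diff| == M does not count
  expect_length(true_positive_set(100, 120, M = 20), 0)
})

test_that("precision/recall/F1 reproduce the worked fractions", {
  got <- precision_recall_f1(c(200, 400), 205, M = 20)
  expect_equal(unname(got), c(1, 0.5, 2/3))
  expect_equal(unname(precision_recall_f1(c(50, 150), c(50, 150), M = 5)),
               c(1, 1, 1))
  expect_equal(unname(precision_recall_f1(c(50, 150), integer(0), M = 5)),
               c(0, 0, 0))
  # two predictions near one true point halve precision
  expect_equal(unname(precision_recall_f1(100, c(95, 105), M = 20))[1], 0.5)
  expect_error(precision_recall_f1(integer(0), 5, M = 2), "ground-truth")
})

test_that("margin AUC ranks labels with mid-rank ties", {
  # perfect separation
  s <- c(0.1, 0.2, 0.9, 1.0, 0.15)
  expect_equal(margin_auc(s, tau = 3, M = 1, t = 1:5), 1)
  # all scores equal -> 0.5
  expect_equal(margin_auc(rep(1, 100), tau = 50, M = 5, t = 1:100), 0.5)
  # invariance under strictly increasing transforms
  set.seed(41)
  s2 <- runif(200)
  a1 <- margin_auc(s2, tau = c(60, 140), M = 10, t = 1:200)
  a2 <- margin_auc(exp(3 * s2) + 5, tau = c(60, 140), M = 10, t = 1:200)
  expect_equal(a1, a2)
  # independence null: AUC near 0.5
  set.seed(42)
  s3 <- rnorm(1e4)
  null_auc <- margin_auc(s3, tau = seq(500, 9500, by = 1000), M = 50,
                         t = seq_len(1e4))
  expect_lt(abs(null_auc - 0.5), 0.03)
  expect_error(margin_auc(s, tau = 100, M = 1, t = 1:5), "class 1")
})

test_that("rand index matches hand counts and the all-pairs oracle", {
  expect_equal(rand_index(c(4), c(4), N = 6), 1)
  expect_equal(rand_index(c(4), integer(0), N = 6), 6 / 15)
  brute_ri <- function(tau, tau_hat, N) {
    a <- findInterval(seq_len(N), sort(tau))
    b <- findInterval(seq_len(N), sort(tau_hat))
    agree <- 0
    for (i in seq_len(N - 1))
      for (j in seq.int(i + 1, N))
        agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    agree / choose(N, 2)
  }
  set.seed(43)
  for (rep in 1:8) {
    N <- sample(5:40, 1)
    tau <- sort(sample(2:N, sample(0:3, 1)))
    tau_hat <- sort(sample(2:N, sample(0:4, 1)))
    expect_equal(rand_index(tau, tau_hat, N), brute_ri(tau, tau_hat, N),
                 label = sprintf("N=%d", N))
  }
})

test_that("evaluate_scores bundles all metrics against ground truth", {
  sf <- step_fixture(N = 300, tau = 150, amplitude = 4)
  fit <- cpd(sf$series[[1]], "knn", h = 20, lag = 5, k = 2)
  ev <- evaluate_scores(fit, tau = 150, M = 30)
  expect_s3_class(ev, "cpd_eval")
  for (f in c("auc", "precision", "recall", "f1", "rand_index"))
    expect_true(ev[[f]] >= 0 && ev[[f]] <= 1)
  expect_gt(ev$auc, 0.7)
  expect_equal(ev$recall, 1)
})

test_that("grid search returns the AUC-maximising configuration", {
  sf <- step_fixture(N = 240, tau = 120, amplitude = 4)
  x <- sf$series[[1]]
  # singleton grid is returned as-is
  gs1 <- grid_search_best_auc(x, 120, method = "sst",
                              grids = list(h = 20, r_hat = 2), M = 25)
  expect_equal(gs1$best_params$h, 20)
  expect_equal(gs1$best_params$r_hat, 2)
  # the winner attains the max of the table
  gs <- grid_search_best_auc(x, 120, method = "knn",
                             grids = list(h = c(20, 40), k = c(1, 3)),
                             M = 25)
  expect_equal(gs$best_auc, max(gs$table$auc, na.rm = TRUE))
  expect_equal(gs$result$auc, gs$best_auc)
  # ties break towards the smaller h (identical scores on duplicated grid)
  gs2 <- grid_search_best_auc(x, 120, method = "hotelling_t2",
                              grids = list(h = c(20, 20)), M = 25)
  expect_equal(gs2$best_params$h, 20)
  expect_error(grid_search_best_auc(x, 120, method = "knn",
                                    grids = list(h = integer(0))), "empty")
})
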