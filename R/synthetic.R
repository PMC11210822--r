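new_cpd_dataset <- function(series, truths, spec, params = NULL) {
  structure(list(series = series, truths = truths, spec = spec,
                 params = params),
            class = "cpd_dataset")
}

#' @export
print.cpd_dataset <- function(x, ...) {
  n <- length(x$series)
  dims <- dim(x$series[[1]])
  cat(sprintf("cpd_dataset (%s): %d sample(s) of %d x %d (time x channel)\n",
              x$spec$kind, n, dims[1], dims[2]))
  cat(sprintf("  true change points per sample: %d\n", length(x$truths[[1]])))
  invisible(x)
}

check_period <- function(N, period) {
  if (period < 1L || N %% period != 0L || N %/% period < 2L)
    stop("`period` must divide `N` into at least 2 segments")
  seq.int(period, N - period, by = period)
}

#' Synthetic mean-shift benchmark family
#'
#' Generates `n_samples` independent samples of `m`-channel Gaussian series
#' of length `N` in which the mean jumps at every change point
#' (`period, 2 period, ..., N - period`; a change point is the first index
#' of its new regime). Within each segment the values are i.i.d.
#' `Normal(mu_seg, base_sd^2)` per channel; at each change point each
#' channel's mean moves by a signed shift `s * delta` with
#' `delta ~ Uniform(shift_low, shift_high)` and equiprobable sign, so change
#' magnitudes vary across points and channels.
#'
#' Defaults match the benchmark conditions: 10 samples of 10-channel series
#' of length 2000 with a change point every 200 points.
#'
#' @param n_samples Number of samples.
#' @param m Channels per sample.
#' @param N Series length.
#' @param period Change-point spacing.
#' @param shift_low,shift_high Bounds of the shift magnitude
#'   (`0 <= shift_low <= shift_high`).
#' @param base_sd Within-segment noise SD.
#' @param seed Optional integer seed.
#' @return A `"cpd_dataset"`: lists `series` (N x m matrices) and `truths`
#'   (integer change points), the generating `spec`, and `params` holding
#'   the drawn segment means (`n_segments x m` per sample) for oracle
#'   checks.
#' @export
mean_shift_dataset <- function(n_samples = 10L, m = 10L, N = 2000L,
                               period = 200L, shift_low = 0.5,
                               shift_high = 3, base_sd = 1, seed = NULL) {
  if (shift_low < 0 || shift_high < shift_low)
    stop("need 0 <= shift_low <= shift_high")
  tau <- check_period(N, period)
  n_seg <- N %/% period
  if (!is.null(seed)) set.seed(seed)
  series <- vector("list", n_samples)
  mus <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    mu <- matrix(0, n_seg, m)
    for (j in seq_len(m)) {
      for (g in seq.int(2L, n_seg)) {
        delta <- stats::runif(1, shift_low, shift_high)
        sgn <- sample(c(-1, 1), 1L)
        mu[g, j] <- mu[g - 1L, j] + sgn * delta
      }
    }
    X <- matrix(stats::rnorm(N * m, mean = mu[rep(seq_len(n_seg),
                                                  each = period), ],
                             sd = base_sd), N, m)
    series[[s]] <- X
    mus[[s]] <- mu
  }
  new_cpd_dataset(series, rep(list(tau), n_samples),
                  spec = list(kind = "mean_shift", n_samples = n_samples,
                              m = m, N = N, period = period,
                              shift_low = shift_low, shift_high = shift_high,
                              base_sd = base_sd, seed = seed),
                  params = list(mu = mus))
}

#' Synthetic variance-shift benchmark family
#'
#' Zero-mean Gaussian series whose per-segment SD is drawn log-uniformly
#' from `[1/sd_range, sd_range]`, with consecutive segments forced to differ
#' by an SD ratio of at least `min_ratio` (redrawn otherwise), so every
#' labelled change point is a real variance change. Change points and
#' defaults are as in [mean_shift_dataset()].
#'
#' @inheritParams mean_shift_dataset
#' @param sd_range Upper bound of the log-uniform SD range (default 3).
#' @param min_ratio Minimum SD ratio between consecutive segments
#'   (default 1.5).
#' @return A `"cpd_dataset"`; `params$sd` holds the drawn segment SDs.
#' @export
variance_shift_dataset <- function(n_samples = 10L, m = 10L, N = 2000L,
                                   period = 200L, sd_range = 3,
                                   min_ratio = 1.5, seed = NULL) {
  if (sd_range < 1) stop("`sd_range` must be >= 1")
  if (min_ratio < 1) stop("`min_ratio` must be >= 1")
  if (min_ratio > sd_range^2)
    stop("`min_ratio` unattainable within the SD range")
  tau <- check_period(N, period)
  n_seg <- N %/% period
  if (!is.null(seed)) set.seed(seed)
  draw_sd <- function() exp(stats::runif(1, -log(sd_range), log(sd_range)))
  series <- vector("list", n_samples)
  sds <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    sd_seg <- matrix(0, n_seg, m)
    for (j in seq_len(m)) {
      sd_seg[1L, j] <- draw_sd()
      for (g in seq.int(2L, n_seg)) {
        repeat {
          cand <- draw_sd()
          ratio <- max(cand / sd_seg[g - 1L, j], sd_seg[g - 1L, j] / cand)
          if (ratio >= min_ratio) break
        }
        sd_seg[g, j] <- cand
      }
    }
    X <- matrix(stats::rnorm(N * m, 0,
                             sd = sd_seg[rep(seq_len(n_seg), each = period), ]),
                N, m)
    series[[s]] <- X
    sds[[s]] <- sd_seg
  }
  new_cpd_dataset(series, rep(list(tau), n_samples),
                  spec = list(kind = "variance_shift", n_samples = n_samples,
                              m = m, N = N, period = period,
                              sd_range = sd_range, min_ratio = min_ratio,
                              seed = seed),
                  params = list(sd = sds))
}

#' Deterministic single-step fixture
#'
#' A noiseless one-channel piecewise-constant series: 0 before `tau`,
#' `amplitude` from `tau` on. Used as the localisation fixture for all
#' scoring methods.
#'
#' @param N Series length.
#' @param tau Step position (`1 < tau < N`), the first index of the new
#'   level.
#' @param amplitude Step height.
#' @return A `"cpd_dataset"` with one sample and truth `tau`.
#' @export
step_fixture <- function(N = 200L, tau = 100L, amplitude = 5) {
  N <- as.integer(N); tau <- as.integer(tau)
  if (is.na(tau) || tau <= 1L || tau >= N)
    stop("`tau` must satisfy 1 < tau < N")
  x <- matrix(c(rep(0, tau - 1L), rep(amplitude, N - tau + 1L)), ncol = 1L)
  new_cpd_dataset(list(x), list(tau),
                  spec = list(kind = "step_fixture", N = N, tau = tau,
                              amplitude = amplitude))
}

#' Synthetic respiration-like series with apnea intervals
#'
#' A qualitative, synthetic stand-in for a contact-free respiration sensor
#' recording: three amplitude-modulated quasi-periodic channels with slow
#' baseline drift whose oscillation amplitude collapses inside the given
#' apnea (breath-hold) intervals, plus Gaussian sensor noise. The labelled
#' change points are the start and end of every interval. This generator
#' does not attempt to clone real radar waveform morphology.
#'
#' @param N Series length.
#' @param apnea_intervals List of `c(start, end)` pairs within `[1, N]`,
#'   non-overlapping.
#' @param noise_sd Gaussian noise SD.
#' @param seed Optional integer seed.
#' @return A `"cpd_dataset"` with one 3-channel sample; truths are the
#'   interval endpoints.
#' @export
respiration_like <- function(N = 4000L, apnea_intervals = list(),
                             noise_sd = 0.05, seed = NULL) {
  N <- as.integer(N)
  iv <- lapply(apnea_intervals, function(p) {
    p <- as.integer(p)
    if (length(p) != 2L || anyNA(p) || p[1] < 1L || p[2] > N || p[1] >= p[2])
      stop("each apnea interval must be c(start, end) with 1 <= start < end <= N")
    p
  })
  if (length(iv) > 1L) {
    o <- order(vapply(iv, `[`, integer(1), 1L))
    iv <- iv[o]
    for (i in seq.int(2L, length(iv)))
      if (iv[[i]][1] <= iv[[i - 1L]][2]) stop("apnea intervals overlap")
  }
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(N)
  envelope <- 1 + 0.3 * sin(2 * pi * t / (N / 2.7))
  apnea_mask <- rep(FALSE, N)
  for (p in iv) apnea_mask[p[1]:p[2]] <- TRUE
  envelope[apnea_mask] <- envelope[apnea_mask] * 0.05
  periods <- c(37, 41, 43)
  phases <- stats::runif(3, 0, 2 * pi)
  X <- vapply(1:3, function(j) {
    carrier <- envelope * sin(2 * pi * t / periods[j] + phases[j])
    drift <- 0.2 * sin(2 * pi * t / N + phases[j] / 2)
    carrier + drift + stats::rnorm(N, 0, noise_sd)
  }, numeric(N))
  truths <- sort(unlist(lapply(iv, identity)))
  new_cpd_dataset(list(X), list(as.integer(truths)),
                  spec = list(kind = "respiration_like", N = N,
                              apnea_intervals = iv, noise_sd = noise_sd,
                              seed = seed),
                  params = list(envelope = envelope))
}
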