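#' Window configuration for sub-sequence change-point scoring
#'
#' Bundles the Hankel window parameters: window size `h` (points per column),
#' the number of columns `r1`/`r2` in the past and current windows, the lag
#' `L` between them, and the evaluation stride.
#'
#' Defaults follow the convention `r1 = r2 = max(2, floor(h/2))` and
#' `lag = floor(h/4)`; both are freely configurable. Diffusion-map scoring
#' additionally requires `r1 == r2` so that the embedded windows can be
#' differenced row-for-row.
#'
#' @param h Window size in points (`>= 2`).
#' @param r1 Number of columns in the past window (`>= 2`).
#' @param r2 Number of columns in the current window (`>= 2`).
#' @param lag Non-negative lag `L` between the two windows, in points.
#' @param stride Step between evaluated time points (`>= 1`).
#' @return An object of class `"window_config"`.
#' @examples
#' window_config(h = 20)
#' window_config(h = 40, r1 = 10, r2 = 10, lag = 10)
#' @export
window_config <- function(h, r1 = NULL, r2 = NULL, lag = NULL, stride = 1L) {
  h <- as.integer(h)
  if (is.na(h) || h < 2L) stop("`h` must be an integer >= 2")
  if (is.null(r1)) r1 <- max(2L, h %/% 2L)
  if (is.null(r2)) r2 <- r1
  r1 <- as.integer(r1); r2 <- as.integer(r2)
  if (is.na(r1) || r1 < 2L) stop("`r1` must be an integer >= 2")
  if (is.na(r2) || r2 < 2L) stop("`r2` must be an integer >= 2")
  if (is.null(lag)) lag <- h %/% 4L
  lag <- as.integer(lag)
  if (is.na(lag) || lag < 0L) stop("`lag` must be a non-negative integer")
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("`stride` must be an integer >= 1")
  structure(list(h = h, r1 = r1, r2 = r2, lag = lag, stride = stride),
            class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("window_config: h = %d, r1 = %d, r2 = %d, lag = %d, stride = %d\n",
              x$h, x$r1, x$r2, x$lag, x$stride))
  invisible(x)
}

# Coerce input series to an N x m numeric matrix (time x channel).
as_series_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  if (!is.numeric(x)) stop("series must be numeric")
  if (!all(is.finite(x))) stop("series contains non-finite values")
  x
}

#' Build a past/current Hankel window pair from a single channel
#'
#' Extracts the past window `P` and current window `Q` at evaluation time
#' `t` (1-based). `P` has columns starting at `t - r1 - h + 1, ..., t - h`
#' and `Q` the same starts shifted by `+lag`; each column is the `h`
#' consecutive points from its start. Adjacent columns therefore overlap by
#' `h - 1` points (Hankel structure), and `P` covers data strictly before
#' `t`.
#'
#' @param x Numeric vector, one channel of the series.
#' @param t Evaluation time index (1-based). The earliest valid `t` is
#'   `r1 + h`; the latest is `length(x) - lag + 1`.
#' @param config A [window_config()].
#' @return A list of class `"window_pair"` with matrices `P` (`h x r1`),
#'   `Q` (`h x r2`), the time `t` and the `config`.
#' @examples
#' wp <- build_window_pair(1:10, t = 6, window_config(h = 2, r1 = 2, lag = 1))
#' wp$P  # columns (3,4) and (4,5)
#' wp$Q  # columns (4,5) and (5,6)
#' @export
build_window_pair <- function(x, t, config) {
  stopifnot(inherits(config, "window_config"))
  x <- as.numeric(x)
  n <- length(x)
  h <- config$h; r1 <- config$r1; r2 <- config$r2; L <- config$lag
  t <- as.integer(t)
  p_first <- t - r1 - h + 1L
  q_first <- t - r2 - h + 1L + L
  if (p_first < 1L || q_first < 1L)
    stop(sprintf(
      "not enough history at t = %d: first window column would start at index %d (need >= 1)",
      t, min(p_first, q_first)))
  q_last_end <- t + L - 1L
  if (q_last_end > n)
    stop(sprintf(
      "not enough horizon at t = %d: current window extends to index %d but the series ends at %d",
      t, q_last_end, n))
  P <- vapply(seq.int(p_first, by = 1L, length.out = r1),
              function(s) x[s:(s + h - 1L)], numeric(h))
  Q <- vapply(seq.int(q_first, by = 1L, length.out = r2),
              function(s) x[s:(s + h - 1L)], numeric(h))
  structure(list(P = P, Q = Q, t = t, config = config), class = "window_pair")
}

#' Build a multichannel Hankel window pair
#'
#' Applies [build_window_pair()] to every channel and concatenates the
#' per-channel windows column-wise in channel order, giving
#' `P` of size `h x (r1 * m)` and `Q` of size `h x (r2 * m)`.
#'
#' @param X Series matrix (time x channel) or numeric vector.
#' @inheritParams build_window_pair
#' @return A `"window_pair"` as in [build_window_pair()].
#' @export
build_multichannel_pair <- function(X, t, config) {
  X <- as_series_matrix(X)
  pairs <- lapply(seq_len(ncol(X)), function(j)
    build_window_pair(X[, j], t, config))
  structure(list(P = do.call(cbind, lapply(pairs, `[[`, "P")),
                 Q = do.call(cbind, lapply(pairs, `[[`, "Q")),
                 t = as.integer(t), config = config),
            class = "window_pair")
}

# First and last valid evaluation times (1-based) for a series of length n.
valid_time_range <- function(n, config) {
  t_min <- max(config$r1 + config$h,
               config$r2 + config$h - config$lag)
  t_max <- n - config$lag + 1L
  c(t_min, t_max)
}

#' Range-normalise each channel to [0, 1]
#'
#' Maps every channel to `(v - min) / (max - min)`. A constant channel is
#' mapped to all zeros rather than raising an error, so degenerate channels
#' do not abort a run. The map is idempotent.
#'
#' @param X Series matrix (time x channel) or numeric vector.
#' @return A matrix of the same shape with every channel in `[0, 1]`.
#' @examples
#' range_normalize(c(2, 4, 6))
#' @export
range_normalize <- function(X) {
  X <- as_series_matrix(X)
  apply(X, 2L, function(v) {
    rng <- range(v)
    if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else rep(0, length(v))
  })
}

#' Add i.i.d. Gaussian noise to a series
#'
#' Adds `Normal(0, sigma_hat^2)` noise element-wise; used for the
#' noise-robustness sweeps where `sigma_hat` is varied over
#' `0.1, 0.2, ..., 1.0`.
#'
#' @param X Series matrix or vector.
#' @param sigma_hat Noise standard deviation (`>= 0`).
#' @param seed Optional integer seed for reproducibility.
#' @return The noisy series matrix.
#' @export
add_gaussian_noise <- function(X, sigma_hat, seed = NULL) {
  X <- as_series_matrix(X)
  if (!is.numeric(sigma_hat) || length(sigma_hat) != 1L || sigma_hat < 0)
    stop("`sigma_hat` must be a single non-negative number")
  if (sigma_hat == 0) return(X)
  if (!is.null(seed)) set.seed(seed)
  X + matrix(stats::rnorm(length(X), 0, sigma_hat), nrow(X), ncol(X))
}

#' Downsample a series by an integer factor
#'
#' Keeps every `factor`-th point, giving `ceiling(N / factor)` points. By
#' default a 4th-order Butterworth low-pass (cutoff 0.8 of the new Nyquist
#' frequency, applied forward-backward so the result is zero-phase) is run
#' before decimation to suppress aliasing; set `anti_alias = FALSE` for
#' naive decimation.
#'
#' @param X Series matrix or vector.
#' @param factor Integer decimation factor (`>= 1`).
#' @param anti_alias Apply the low-pass filter before decimation?
#' @return The downsampled series matrix.
#' @export
downsample <- function(X, factor, anti_alias = TRUE) {
  X <- as_series_matrix(X)
  if (length(factor) != 1L || is.na(factor) || factor < 1 || factor != round(factor))
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(X)
  if (anti_alias) {
    bf <- signal::butter(4, 0.8 / factor)
    n <- nrow(X)
    pad <- min(n - 1L, as.integer(ceiling(15 * factor)))
    X <- apply(X, 2L, function(v) {
      # reflect-pad so the filter's edge transients fall outside the signal
      vp <- c(rev(v[seq_len(pad) + 1L]), v, v[n - seq_len(pad)])
      signal::filtfilt(bf, vp)[pad + seq_len(n)]
    })
  }
  X[seq.int(1L, nrow(X), by = factor), , drop = FALSE]
}

#' Append sliding-frame FFT magnitude channels
#'
#' For each channel, appends a companion channel holding the mean magnitude
#' of the discrete Fourier transform over a sliding frame centred at each
#' time point (hop 1, edges reflected), so the channel count doubles — e.g.
#' 3 sensor features become 6. This is a same-length spectral-energy summary
#' aligned to time; the frame length controls the spectral resolution.
#'
#' @param X Series matrix or vector.
#' @param frame Frame length in points (`2 <= frame <= N`).
#' @return A matrix with `2 m` channels: the originals followed by their
#'   spectral companions (suffix `"_fftmag"`).
#' @export
fft_feature_augment <- function(X, frame = 64L) {
  X <- as_series_matrix(X)
  n <- nrow(X)
  frame <- as.integer(frame)
  if (is.na(frame) || frame < 2L) stop("`frame` must be an integer >= 2")
  if (frame > n) stop(sprintf("`frame` (%d) exceeds the series length (%d)", frame, n))
  left <- (frame - 1L) %/% 2L
  right <- frame - 1L - left
  companion <- apply(X, 2L, function(v) {
    vp <- c(rev(v[seq_len(left) + 1L]), v, v[n - seq_len(right)])
    vapply(seq_len(n), function(t) {
      w <- vp[t:(t + frame - 1L)]
      mean(Mod(stats::fft(w)))
    }, numeric(1))
  })
  out <- cbind(X, companion)
  base <- colnames(X)
  if (is.null(base)) base <- paste0("ch", seq_len(ncol(X)))
  colnames(out) <- c(base, paste0(base, "_fftmag"))
  out
}
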