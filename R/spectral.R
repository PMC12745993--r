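# Spectral estimation: Welch PSD in dB, IRASA fractal/oscillatory split,
# and Gaussian smoothing of the oscillatory component. No external signal
# processing package is used; everything is built on stats::fft/mvfft.

POWER_FLOOR <- 1e-12  # uV^2/Hz, clipped before 10*log10 to avoid -Inf

#' Fourier-domain resampling
#'
#' Resamples a series to `n_out` points by zero-padding or truncating its
#' spectrum, i.e. ideal (anti-aliased) band-limited interpolation. Used for
#' the irregular-resampling step of IRASA and for rate conversion of EDF
#' channels.
#'
#' @param x numeric vector, or a matrix with one series per column.
#' @param n_out output length.
#' @return resampled vector/matrix with `n_out` rows.
#' @export
fft_resample <- function(x, n_out) {
  if (is.matrix(x)) return(fft_resample_mat(x, n_out))
  drop(fft_resample_mat(matrix(x, ncol = 1L), n_out))
}

fft_resample_mat <- function(X, n_out) {
  n <- nrow(X)
  n_out <- as.integer(n_out)
  if (n_out < 1L) stop("n_out must be positive")
  if (n_out == n) return(X)
  XF <- stats::mvfft(X)
  YF <- matrix(0 + 0i, n_out, ncol(X))
  m <- min(n, n_out)
  npos <- (m + 1L) %/% 2L            # DC + positive freqs kept (excl. Nyquist)
  YF[seq_len(npos), ] <- XF[seq_len(npos), ]
  nneg <- m %/% 2L                   # negative freqs kept (incl. any Nyquist)
  if (nneg > 0L) {
    YF[(n_out - nneg + 1L):n_out, ] <- XF[(n - nneg + 1L):n, ]
  }
  # x was real in all uses; Re() discards the tiny asymmetry left by
  # truncating at the new Nyquist bin.
  Re(stats::mvfft(YF, inverse = TRUE)) / n
}

# Hamming window of length n (periodic form is not needed for Welch).
hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Welch PSD of many equal-length series at once.
# X: n_series x n_samples. Returns power in uV^2/Hz (one-sided) and freqs.
welch_power <- function(X, fs, nperseg, noverlap) {
  n <- ncol(X)
  if (nperseg > n) stop("segment longer than the series")
  step <- nperseg - noverlap
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  w <- hamming_window(nperseg)
  U <- fs * sum(w^2)                 # window power normalization
  nf <- nperseg %/% 2L + 1L
  acc <- matrix(0, nrow(X), nf)
  for (s in starts) {
    seg <- X[, s:(s + nperseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)       # constant detrend per segment
    seg <- sweep(seg, 2L, w, "*")
    Z <- stats::mvfft(t(seg))
    acc <- acc + t(Mod(Z[seq_len(nf), , drop = FALSE])^2) / U
  }
  P <- acc / length(starts)
  if (nf > 2L) P[, 2L:(nf - 1L)] <- 2 * P[, 2L:(nf - 1L)]  # one-sided
  list(power = P, freqs = seq(0, fs / 2, length.out = nf))
}

#' Per-epoch Welch power spectral density in decibels
#'
#' Each 30-s epoch is split into Hamming-windowed segments (default 5 s,
#' 50% overlap, giving 0.2 Hz resolution at 100 Hz), periodograms are
#' averaged, and power density is converted to dB (`10*log10`, floored at
#' 1e-12 uV^2/Hz so silent epochs stay finite).
#'
#' @param ep an `epoched_signal` from [segment_epochs()].
#' @param cfg configuration list, see [ais_config()]; uses
#'   `welch$segment_s` and `welch$overlap`.
#' @return a `psd_matrix`: list with `values` (n_epochs x n_freqs, dB),
#'   `freqs` (Hz) and `resolution` (Hz).
#' @export
welch_psd_db <- function(ep, cfg = ais_config()) {
  stopifnot(inherits(ep, "epoched_signal"))
  bad <- which(!is.finite(ep$epochs))
  if (length(bad)) {
    stop("non-finite sample in epoch ", row(ep$epochs)[bad[1L]])
  }
  fs <- ep$sampling_rate
  nperseg <- as.integer(round(cfg$welch$segment_s * fs))
  noverlap <- as.integer(round(nperseg * cfg$welch$overlap))
  wp <- welch_power(ep$epochs, fs, nperseg, noverlap)
  vals <- 10 * log10(pmax(wp$power, POWER_FLOOR))
  psd_matrix(vals, wp$freqs)
}

#' @rdname welch_psd_db
#' @param values dB matrix, epochs in rows.
#' @param freqs frequency grid in Hz.
#' @export
psd_matrix <- function(values, freqs) {
  stopifnot(is.matrix(values), ncol(values) == length(freqs),
            all(is.finite(values)), !is.unsorted(freqs, strictly = TRUE))
  structure(list(values = values, freqs = freqs,
                 resolution = freqs[2L] - freqs[1L]),
            class = "psd_matrix")
}

#' @export
print.psd_matrix <- function(x, ...) {
  cat(sprintf("<psd_matrix> %d epochs x %d bins (%g-%g Hz @ %g Hz)\n",
              nrow(x$values), length(x$freqs), min(x$freqs), max(x$freqs),
              x$resolution))
  invisible(x)
}

# elementwise median across the columns of a matrix, vectorized via a
# single order() call (rows are sorted in place).
row_medians <- function(X) {
  k <- ncol(X)
  S <- matrix(X[order(row(X), X)], ncol = k, byrow = TRUE)
  if (k %% 2L) S[, (k + 1L) %/% 2L] else (S[, k %/% 2L] + S[, k %/% 2L + 1L]) / 2
}

#' IRASA decomposition into fractal and oscillatory components
#'
#' Irregular-resampling auto-spectral analysis: each epoch is resampled by
#' a set of non-integer factors h and 1/h; a self-affine 1/f background is
#' invariant under the geometric mean of the h and 1/h spectra, while
#' narrow-band oscillations are displaced and suppressed. The fractal
#' spectrum is the median over h of those geometric means; the oscillatory
#' component is the residual, computed in dB so that `psd_fra + psd_osc`
#' reconstructs the Welch PSD exactly.
#'
#' @param ep an `epoched_signal`.
#' @param h_set resampling factors, all > 1 (default 1.1 to 1.9 in steps
#'   of 0.05, taken from `cfg$irasa`).
#' @param cfg configuration list.
#' @return a `spectral_decomposition`: list with `psd_fra`, `psd_osc`
#'   (dB matrices), `psd` (the parent PSD, dB), `freqs`, and
#'   `smoothed = FALSE`.
#' @export
irasa_decompose <- function(ep, h_set = NULL, cfg = ais_config()) {
  stopifnot(inherits(ep, "epoched_signal"))
  if (is.null(h_set)) {
    h_set <- seq(cfg$irasa$h_min, cfg$irasa$h_max, by = cfg$irasa$h_step)
  }
  if (any(h_set <= 1)) stop("all resampling factors h must exceed 1")
  fs <- ep$sampling_rate
  nperseg <- as.integer(round(cfg$welch$segment_s * fs))
  noverlap <- as.integer(round(nperseg * cfg$welch$overlap))
  parent <- welch_psd_db(ep, cfg)
  n <- ncol(ep$epochs)
  Xt <- t(ep$epochs)                       # samples x epochs, resampled as columns
  geo <- vector("list", length(h_set))
  for (j in seq_along(h_set)) {
    h <- h_set[j]
    up <- t(fft_resample_mat(Xt, round(n * h)))
    dn <- t(fft_resample_mat(Xt, round(n / h)))
    p_up <- welch_power(up, fs, nperseg, noverlap)$power
    p_dn <- welch_power(dn, fs, nperseg, noverlap)$power
    geo[[j]] <- sqrt(p_up * p_dn)
  }
  stacked <- matrix(unlist(geo, use.names = FALSE), ncol = length(h_set))
  fra_pow <- matrix(row_medians(stacked), nrow = nrow(parent$values))
  fra_db <- 10 * log10(pmax(fra_pow, POWER_FLOOR))
  # the h-fold compressed spectra carry no content above fs/(2*h_max), so
  # the fractal fit is only valid below that corner; the decomposition grid
  # is truncated there (all downstream consumers use <= 20 Hz anyway)
  valid <- parent$freqs <= fs / (2 * max(h_set))
  structure(list(psd_fra = fra_db[, valid, drop = FALSE],
                 psd_osc = (parent$values - fra_db)[, valid, drop = FALSE],
                 psd = parent$values[, valid, drop = FALSE],
                 freqs = parent$freqs[valid],
                 resolution = parent$resolution, smoothed = FALSE),
            class = "spectral_decomposition")
}

# reflect an out-of-range index into 1..n (half-sample symmetric boundary,
# which conserves mass under symmetric kernels)
reflect_idx <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  j + 1L
}

# separable Gaussian smoothing along one margin of a matrix
gauss_smooth_margin <- function(M, sigma, margin) {
  if (sigma <= 1e-8) return(M)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  g <- stats::dnorm((-r):r, sd = sigma)
  g <- g / sum(g)
  if (margin == 2L) return(t(gauss_smooth_margin(t(M), sigma, 1L)))
  n <- nrow(M)
  P <- M[reflect_idx(seq.int(1L - r, n + r), n), , drop = FALSE]
  out <- matrix(0, n, ncol(M))
  for (t in seq_along(g)) {
    out <- out + g[t] * P[(t):(t + n - 1L), , drop = FALSE]
  }
  out
}

#' Smooth the oscillatory component with a 2-D Gaussian filter
#'
#' Separable Gaussian smoothing over the time axis (epochs) and frequency
#' axis, with symmetric (reflective) boundary handling. The fractal
#' component is left untouched.
#'
#' @param dec a `spectral_decomposition`.
#' @param sigma_time standard deviation along the epoch axis, in epochs.
#' @param sigma_freq standard deviation along the frequency axis, in Hz.
#' @return the decomposition with `psd_osc` replaced by its smoothed copy
#'   and `smoothed = TRUE`.
#' @export
smooth_psd_osc <- function(dec, sigma_time = 1, sigma_freq = 0.5) {
  stopifnot(inherits(dec, "spectral_decomposition"),
            sigma_time >= 0, sigma_freq >= 0)
  sigma_bins <- sigma_freq / dec$resolution
  sm <- gauss_smooth_margin(dec$psd_osc, sigma_time, 1L)
  sm <- gauss_smooth_margin(sm, sigma_bins, 2L)
  dec$psd_osc <- sm
  dec$smoothed <- TRUE
  dec
}

#' Long-format export of a PSD matrix
#'
#' @param x a `psd_matrix`.
#' @param ... unused.
#' @return data.frame with columns `epoch`, `frequency`, `value`.
#' @export
as.data.frame.psd_matrix <- function(x, ...) {
  data.frame(epoch = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
             frequency = rep(x$freqs, each = nrow(x$values)),
             value = as.vector(x$values))
}
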