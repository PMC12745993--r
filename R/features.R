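# Per-epoch staging features: gamma band power, Otsu thresholding,
# personalized fast-spindle band and power, slow-oscillation detection and
# coverage, and oscillatory strength.

#' Mean band power per epoch
#'
#' Mean of the dB values over frequency bins strictly inside the band
#' (`band_low < f < band_high`).
#'
#' @param psd a `psd_matrix`, or a `spectral_decomposition` when
#'   `source = "psd_osc"`.
#' @param band length-2 numeric, Hz, low < high.
#' @param source `"psd"` (default) or `"psd_osc"` for the oscillatory
#'   residual of a decomposition.
#' @return numeric vector, one value per epoch.
#' @export
band_power <- function(psd, band, source = c("psd", "psd_osc")) {
  source <- match.arg(source)
  if (length(band) != 2L || band[1L] >= band[2L]) {
    stop("band must be (low, high) with low < high")
  }
  if (inherits(psd, "spectral_decomposition")) {
    vals <- if (source == "psd_osc") psd$psd_osc else psd$psd
    freqs <- psd$freqs
  } else {
    stopifnot(inherits(psd, "psd_matrix"))
    vals <- psd$values
    freqs <- psd$freqs
  }
  sel <- freqs > band[1L] & freqs < band[2L]
  if (!any(sel)) stop("no frequency bins inside the band")
  rowMeans(vals[, sel, drop = FALSE])
}

#' Otsu histogram threshold
#'
#' The value series is binned into `n_bins` equal-width bins; the returned
#' threshold is the interior bin edge maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`. Ties are broken toward the lowest threshold.
#'
#' @param values numeric vector with at least two distinct values.
#' @param n_bins histogram bins (classic image convention: 256).
#' @return the threshold value.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  rng <- range(values)
  if (diff(rng) == 0) stop("degenerate distribution: all values identical")
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  bin <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  p <- cnt / sum(cnt)
  w0 <- cumsum(p)                      # mass at or below each bin
  m0 <- cumsum(p * mids)
  mt <- m0[n_bins]
  w1 <- 1 - w0
  # candidate thresholds: edges after bins 1..n_bins-1
  k <- seq_len(n_bins - 1L)
  valid <- w0[k] > 0 & w1[k] > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mt * w0[k][valid] - m0[k][valid])^2 /
    (w0[k][valid] * w1[k][valid])
  best <- which.max(bcv)               # which.max takes the first maximum
  edges[best + 1L]
}

#' Personalized fast-spindle band
#'
#' For every epoch the peak frequency of the (smoothed) oscillatory
#' component is located within the search range; a Gaussian kernel density
#' over those per-epoch peaks (Scott 1-D bandwidth, evaluated on a 0.05 Hz
#' grid) summarizes the night, and the local maximum closest to the target
#' frequency — preferring maxima inside the fast-spindle range — defines
#' the band center. The band is the center +/- 1 Hz.
#'
#' @param dec a smoothed `spectral_decomposition`.
#' @param cfg configuration; uses `staging$spindle_search` (default 5-20
#'   Hz), `staging$spindle_target` (14 Hz), `staging$spindle_pref`
#'   (12-16 Hz).
#' @return a `spindle_band`: list with `f_peak`, `low`, `high`,
#'   `peak_freqs` (per-epoch argmax), and `fallback` (`TRUE` when no local
#'   maximum existed and the target frequency was used).
#' @export
personalized_spindle_band <- function(dec, cfg = ais_config()) {
  stopifnot(inherits(dec, "spectral_decomposition"))
  search <- cfg$staging$spindle_search
  target <- cfg$staging$spindle_target
  pref <- cfg$staging$spindle_pref
  sel <- which(dec$freqs >= search[1L] & dec$freqs <= search[2L])
  if (length(sel) < 3L) stop("search range too narrow for the grid")
  sub <- dec$psd_osc[, sel, drop = FALSE]
  f_i <- dec$freqs[sel][max.col(sub, ties.method = "first")]
  n <- length(f_i)
  bw <- stats::sd(f_i) * n^(-1 / 5)
  if (!is.finite(bw) || bw < 0.1) bw <- 0.1
  grid <- seq(search[1L], search[2L], by = 0.05)
  dens <- vapply(grid, function(g) sum(stats::dnorm(g, f_i, bw)), 0) / n
  interior <- 2L:(length(grid) - 1L)
  is_max <- dens[interior] > dens[interior - 1L] &
    dens[interior] >= dens[interior + 1L]
  maxima <- grid[interior][is_max]
  fallback <- FALSE
  if (length(maxima) == 0L) {
    warning("no local maximum in the spindle search range; using ",
            target, " Hz")
    f_peak <- target
    fallback <- TRUE
  } else {
    inside <- maxima[maxima >= pref[1L] & maxima <= pref[2L]]
    pool <- if (length(inside)) inside else maxima
    f_peak <- pool[which.min(abs(pool - target))]
  }
  structure(list(f_peak = f_peak, low = f_peak - 1, high = f_peak + 1,
                 peak_freqs = f_i, fallback = fallback),
            class = "spindle_band")
}

#' Personalized spindle-band power per epoch
#'
#' Mean power over the personalized band. The default source is the raw
#' PSD in dB (whose zero crossing sits near 1 uV^2/Hz, the natural split
#' between spindle-band activity and background at these frequencies);
#' `cfg$psp$source = "psd_osc"` uses the oscillatory residual instead.
#'
#' @param dec a smoothed `spectral_decomposition`.
#' @param band a `spindle_band`.
#' @param cfg configuration.
#' @return numeric vector, one dB value per epoch.
#' @export
spindle_power <- function(dec, band, cfg = ais_config()) {
  stopifnot(inherits(band, "spindle_band"))
  band_power(dec, c(band$low, band$high),
             source = match.arg(cfg$psp$source, c("psd", "psd_osc")))
}

# ---- slow oscillations ----------------------------------------------------

# Zero-phase band-pass via a centred symmetric windowed-sinc (Hamming) FIR,
# applied in one pass with FFT convolution. A symmetric centred kernel has
# exactly zero phase, which the deflection-duration criteria require.
fir_bandpass <- function(x, fs, band, transition = 0.2) {
  ntaps <- as.integer(ceiling(3.3 * fs / transition))
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  m <- (ntaps - 1L) / 2L
  k <- (-m):m
  sinc <- function(fc) {
    h <- 2 * fc / fs * sin(pi * 2 * fc / fs * k) / (pi * 2 * fc / fs * k)
    h[k == 0L] <- 2 * fc / fs
    h
  }
  h <- (sinc(band[2L]) - sinc(band[1L])) * hamming_window(ntaps)
  nf <- stats::nextn(length(x) + ntaps - 1L, 2L)
  Y <- stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                    stats::fft(c(h, numeric(nf - ntaps))),
                  inverse = TRUE) / nf
  Re(Y)[(m + 1L):(m + length(x))]
}

#' Detect slow oscillations
#'
#' The recording is band-pass filtered to 0.5-2.0 Hz (zero-phase FIR).
#' Candidate waves run from one negative-going zero crossing to the next,
#' with the negative deflection first; a candidate is an event iff all five
#' criteria hold: peak-to-peak amplitude > 75 uV, negative deflection
#' 0.3-1.5 s, positive deflection 0.1-1.0 s, negative peak < -10 uV,
#' positive peak > 10 uV.
#'
#' @param rec an [eeg_recording()] at 100 Hz in microvolts.
#' @param cfg configuration; criteria live in `cfg$so`.
#' @return data.frame of events with columns `start_s`, `end_s`,
#'   `neg_peak_uv`, `pos_peak_uv`, `ptp_uv`, `neg_duration_s`,
#'   `pos_duration_s` (zero rows when nothing qualifies).
#' @export
detect_slow_oscillations <- function(rec, cfg = ais_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$duration_s < 4) stop("recording shorter than 4 s")
  fs <- rec$sampling_rate
  z <- fir_bandpass(rec$samples, fs, cfg$so$band, cfg$so$transition)
  n <- length(z)
  neg_cross <- which(z[-n] >= 0 & z[-1L] < 0)       # sample before crossing
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      neg_peak_uv = numeric(0), pos_peak_uv = numeric(0),
                      ptp_uv = numeric(0), neg_duration_s = numeric(0),
                      pos_duration_s = numeric(0))
  if (length(neg_cross) < 2L) return(empty)
  out <- vector("list", length(neg_cross) - 1L)
  for (i in seq_len(length(neg_cross) - 1L)) {
    a <- neg_cross[i] + 1L
    b <- neg_cross[i + 1L]
    seg <- z[a:b]
    pos_cross <- which(seg[-length(seg)] < 0 & seg[-1L] >= 0)
    if (length(pos_cross) != 1L) next     # not a clean two-phase wave
    neg_phase <- seg[1:pos_cross]
    pos_phase <- seg[(pos_cross + 1L):length(seg)]
    neg_peak <- min(neg_phase)
    pos_peak <- max(pos_phase)
    neg_dur <- pos_cross / fs
    pos_dur <- (length(seg) - pos_cross) / fs
    ptp <- pos_peak - neg_peak
    ok <- ptp > cfg$so$ptp_min_uv &&
      neg_peak < cfg$so$neg_peak_max_uv &&
      pos_peak > cfg$so$pos_peak_min_uv &&
      neg_dur > cfg$so$neg_dur_s[1L] && neg_dur < cfg$so$neg_dur_s[2L] &&
      pos_dur > cfg$so$pos_dur_s[1L] && pos_dur < cfg$so$pos_dur_s[2L]
    if (!ok) next
    out[[i]] <- data.frame(start_s = (a - 1L) / fs, end_s = b / fs,
                           neg_peak_uv = neg_peak, pos_peak_uv = pos_peak,
                           ptp_uv = ptp, neg_duration_s = neg_dur,
                           pos_duration_s = pos_dur)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Fraction of each epoch covered by slow oscillations
#'
#' Event durations are split proportionally across epoch boundaries and
#' divided by the epoch duration; values are clipped to `[0, 1]`.
#'
#' @param events event table from [detect_slow_oscillations()].
#' @param ep an `epoched_signal` defining the epoch grid.
#' @return numeric vector in `[0, 1]`, one value per epoch.
#' @export
so_percentage <- function(events, ep) {
  stopifnot(inherits(ep, "epoched_signal"))
  n_ep <- nrow(ep$epochs)
  dur <- ep$epoch_duration_s
  cov <- numeric(n_ep)
  for (i in seq_len(nrow(events))) {
    s <- events$start_s[i]; e <- events$end_s[i]
    for (j in seq.int(max(1L, floor(s / dur) + 1L),
                      min(n_ep, floor((e - 1e-12) / dur) + 1L))) {
      lo <- (j - 1L) * dur; hi <- j * dur
      cov[j] <- cov[j] + max(0, min(e, hi) - max(s, lo))
    }
  }
  pmin(pmax(cov / dur, 0), 1)
}

#' Oscillatory strength per epoch
#'
#' Standard deviation of the (smoothed) oscillatory component over bins
#' with `5 < f < 20` Hz — high for epochs dominated by alpha or spindle
#' rhythms. The companion scalar `std_overall` (standard deviation of the
#' entire oscillatory matrix) is attached as an attribute.
#'
#' @param dec a smoothed `spectral_decomposition`.
#' @param cfg configuration; range from `staging$spindle_search`.
#' @return numeric vector per epoch, with attribute `std_overall`.
#' @export
std_osc <- function(dec, cfg = ais_config()) {
  stopifnot(inherits(dec, "spectral_decomposition"))
  rng <- cfg$staging$spindle_search
  sel <- dec$freqs > rng[1L] & dec$freqs < rng[2L]
  v <- apply(dec$psd_osc[, sel, drop = FALSE], 1L, stats::sd)
  attr(v, "std_overall") <- stats::sd(as.vector(dec$psd_osc))
  v
}
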