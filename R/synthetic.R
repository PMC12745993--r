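# Seedable generator of ground-truthed synthetic overnight EEG. Each stage
# has a spectral recipe mirroring its canonical phenomenology: 1/f
# background everywhere; broadband gamma for open-eye Wake; ~10 Hz alpha for
# closed-eye Wake; fast-spindle bursts for N2 (and, sparser, N3);
# high-amplitude 0.5-1.2 Hz slow oscillations for N3; low-amplitude
# mixed-frequency (theta-tinged) activity for both N1 and REM, which are
# deliberately near-identical spectrally so that only the temporal logic
# can separate them.

#' Specification of a synthetic night
#'
#' Amplitudes are in microvolts and were fixed once at physiologically
#' conventional values; the semi-Markov transition model produces sleep
#' cycles beginning and ending in Wake.
#'
#' @param n_epochs number of 30-s epochs (default 960 = 8 h).
#' @param seed RNG seed; all generation is deterministic given the spec.
#' @param ... overrides of the recipe fields (see the returned list).
#' @return a `night_spec` list.
#' @export
night_spec <- function(n_epochs = 960L, seed = 1L, ...) {
  spec <- list(
    n_epochs = as.integer(n_epochs),
    seed = as.integer(seed),
    fs = 100,
    bg_exponent = 1.5,
    # background: a 1/f component common to all stages (amplitude
    # differences between sleep stages live below ~6 Hz in practice, so
    # the broadband floor is stage-independent) plus a stage-specific
    # low-frequency 1/f component
    bg_rms = 10,
    slow_cutoff_hz = 6,
    slow_rms = c(W = 5, N1 = 6, N2 = 10, N3 = 14, REM = 6),
    # each Wake run is eyes-open for its first part (alert) and
    # eyes-closed for the remainder (drowsy, alpha-rich), as in real
    # pre-sleep wakefulness; p_wake_open sets the open fraction of a run
    p_wake_open = 0.5,
    gamma_band = c(25, 50),
    gamma_rms = 10,             # added broadband gamma, open-eye Wake
    alpha_freq_range = c(9.5, 10.5),
    alpha_amp = 25,             # closed-eye Wake alpha, uV
    alpha_duty = 0.6,
    spindle_freq_range = c(12, 16),  # per-night center, sampled once
    spindle_amp = 25,
    spindle_dur_s = c(0.7, 1.5),
    spindle_count_n2 = c(3L, 8L),
    spindle_count_n3 = c(1L, 3L),
    so_freq_range = c(0.5, 1.2),
    so_amp = 60,                # half peak-to-peak, uV (PTP 120 > 75)
    so_coverage = 0.5,          # fraction of each N3 epoch inside SO trains
    theta_freq_range = c(4, 5.5),
    theta_amp = 10,
    theta_duty = 0.5,
    # semi-Markov model: mean run lengths in epochs and transition rows;
    # N1 runs are capped because the stage lasts 1-5 minutes in practice
    run_mean = c(W = 10, N1 = 4, N2 = 30, N3 = 16, REM = 24),
    run_cap = c(W = Inf, N1 = 10, N2 = Inf, N3 = Inf, REM = Inf),
    start_wake_epochs = 20L,
    end_wake_epochs = 10L,
    transitions = rbind(
      W   = c(W = 0,    N1 = 1,    N2 = 0,    N3 = 0,   REM = 0),
      N1  = c(W = 0.10, N1 = 0,    N2 = 0.80, N3 = 0,   REM = 0.10),
      N2  = c(W = 0.05, N1 = 0.10, N2 = 0,    N3 = 0.5, REM = 0.35),
      N3  = c(W = 0.10, N1 = 0,    N2 = 0.90, N3 = 0,   REM = 0),
      REM = c(W = 0.30, N1 = 0.30, N2 = 0.40, N3 = 0,   REM = 0)
    )
  )
  over <- list(...)
  for (nm in names(over)) spec[[nm]] <- over[[nm]]
  if (spec$n_epochs < 40L) stop("n_epochs must be at least 40")
  structure(spec, class = "night_spec")
}

#' Sample a ground-truth hypnogram from the semi-Markov model
#'
#' Runs begin with a fixed Wake block, alternate stages according to the
#' transition matrix with geometric run lengths (mean `run_mean`), and end
#' in Wake.
#'
#' @param spec a [night_spec()].
#' @return a [hypnogram()] of length `spec$n_epochs`.
#' @export
generate_hypnogram <- function(spec) {
  stopifnot(inherits(spec, "night_spec"))
  withr::with_seed(spec$seed, {
    codes <- c(W = 0L, N1 = 1L, N2 = 2L, N3 = 3L, REM = 4L)
    body_len <- spec$n_epochs - spec$end_wake_epochs
    seq_stages <- rep(0L, min(spec$start_wake_epochs, body_len))
    cur <- "W"
    while (length(seq_stages) < body_len) {
      pr <- spec$transitions[cur, ]
      cur <- sample(names(pr), 1L, prob = pr)
      len <- min(1L + stats::rgeom(1L, 1 / spec$run_mean[[cur]]),
                 spec$run_cap[[cur]])
      seq_stages <- c(seq_stages, rep(codes[[cur]], len))
    }
    seq_stages <- seq_stages[seq_len(body_len)]
    hypnogram(c(seq_stages, rep(0L, spec$end_wake_epochs)))
  })
}

# 1/f^alpha noise of length n via spectral shaping, scaled to target RMS;
# `cutoff` (Hz) optionally restricts the shaping to low frequencies
pink_noise <- function(n, alpha, rms, fs, cutoff = Inf) {
  wn <- stats::rnorm(n)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]      # two-sided frequency axis
  shape <- pmax(f, 0.5)^(-alpha / 2)       # flat below 0.5 Hz: no DC blowup
  shape[1L] <- 0
  shape[f > cutoff] <- 0
  x <- Re(stats::fft(stats::fft(wn) * shape, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# band-limited Gaussian noise, scaled to target RMS
band_noise <- function(n, band, rms, fs) {
  wn <- stats::rnorm(n)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  mask <- as.numeric(f >= band[1L] & f <= band[2L])
  x <- Re(stats::fft(stats::fft(wn) * mask, inverse = TRUE)) / n
  if (stats::sd(x) == 0) return(numeric(n))
  x * rms / stats::sd(x)
}

# Hann-enveloped sinusoid burst placed at a random offset inside an epoch
add_burst <- function(x, fs, freq, amp, dur_s) {
  n <- length(x)
  len <- round(dur_s * fs)
  if (len >= n) len <- n - 1L
  start <- sample.int(n - len, 1L)
  t <- seq_len(len) / fs
  env <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1L)))
  x[start:(start + len - 1L)] <- x[start:(start + len - 1L)] +
    amp * env * sin(2 * pi * freq * t + stats::runif(1L, 0, 2 * pi))
  x
}

#' Synthesize a night of EEG from a hypnogram
#'
#' Builds a 100 Hz microvolt signal epoch by epoch according to each
#' epoch's stage recipe. Wake epochs are independently "open" (broadband
#' gamma) or "closed" (alpha bursts) with probability `p_wake_open`; the
#' night's spindle center frequency is sampled once from
#' `spindle_freq_range`.
#'
#' @param h ground-truth [hypnogram()] (codes 0-4).
#' @param spec the [night_spec()] that generated `h`.
#' @return an [eeg_recording()]; the per-epoch wake mode ("open"/"closed"/
#'   NA) is attached as attribute `wake_mode`, the night's spindle center
#'   as `spindle_center`.
#' @export
synthesize_night <- function(h, spec) {
  stopifnot(inherits(spec, "night_spec"))
  h <- hypnogram(h)
  if (length(h) != spec$n_epochs) stop("hypnogram length != spec$n_epochs")
  if (any(unclass(h) == 5L)) stop("ground-truth hypnogram contains Unknown")
  fs <- spec$fs
  ne <- spec$n_epochs
  npts <- as.integer(30 * fs)
  withr::with_seed(spec$seed + 1L, {
    f_spindle <- stats::runif(1L, spec$spindle_freq_range[1L],
                              spec$spindle_freq_range[2L])
    f_alpha <- stats::runif(1L, spec$alpha_freq_range[1L],
                            spec$alpha_freq_range[2L])
    wake_mode <- rep(NA_character_, ne)
    r <- rle(unclass(h))
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (j in which(r$values == 0L)) {
      idx <- run_start[j]:run_end[j]
      n_open <- ceiling(length(idx) * spec$p_wake_open)
      wake_mode[idx] <- c(rep("open", n_open),
                          rep("closed", length(idx) - n_open))
    }
    sig <- matrix(0, ne, npts)
    stage_names <- c("W", "N1", "N2", "N3", "REM")
    for (i in seq_len(ne)) {
      st <- unclass(h)[i]
      x <- pink_noise(npts, spec$bg_exponent, spec$bg_rms, fs) +
        pink_noise(npts, spec$bg_exponent,
                   spec$slow_rms[[stage_names[st + 1L]]], fs,
                   cutoff = spec$slow_cutoff_hz)
      if (st == 0L) {
        if (wake_mode[i] == "open") {
          x <- x + band_noise(npts, spec$gamma_band, spec$gamma_rms, fs)
        } else {
          n_bursts <- max(1L, round(spec$alpha_duty * 30 / 2))
          for (b in seq_len(n_bursts)) {
            x <- add_burst(x, fs, f_alpha, spec$alpha_amp,
                           stats::runif(1L, 1.5, 2.5))
          }
        }
      } else if (st == 2L || st == 3L) {
        cnt_rng <- if (st == 2L) spec$spindle_count_n2 else
          spec$spindle_count_n3
        n_sp <- sample(cnt_rng[1L]:cnt_rng[2L], 1L)
        for (b in seq_len(n_sp)) {
          x <- add_burst(x, fs, f_spindle, spec$spindle_amp,
                         stats::runif(1L, spec$spindle_dur_s[1L],
                                      spec$spindle_dur_s[2L]))
        }
        if (st == 3L) {
          # trains of full slow-oscillation cycles covering ~so_coverage
          covered <- 0
          guard <- 0L
          while (covered < spec$so_coverage * 30 && guard < 50L) {
            guard <- guard + 1L
            f_so <- stats::runif(1L, spec$so_freq_range[1L],
                                 spec$so_freq_range[2L])
            n_cyc <- sample(2:4, 1L)
            dur <- n_cyc / f_so
            len <- round(dur * fs)
            if (len >= npts) next
            start <- sample.int(npts - len, 1L)
            t <- seq_len(len) / fs
            # negative deflection first, matching the detector convention
            x[start:(start + len - 1L)] <- x[start:(start + len - 1L)] -
              spec$so_amp * sin(2 * pi * f_so * t)
            covered <- covered + dur
          }
        }
      } else {
        # N1 and REM: low-amplitude mixed frequency, spectrally similar
        n_bursts <- max(1L, round(spec$theta_duty * 30 / 3))
        for (b in seq_len(n_bursts)) {
          x <- add_burst(x, fs,
                         stats::runif(1L, spec$theta_freq_range[1L],
                                      spec$theta_freq_range[2L]),
                         spec$theta_amp, stats::runif(1L, 1, 3))
        }
      }
      sig[i, ] <- x
    }
    rec <- eeg_recording(as.vector(t(sig)), fs, "synthetic Fpz-Cz")
    attr(rec, "wake_mode") <- wake_mode
    attr(rec, "spindle_center") <- f_spindle
    rec
  })
}

#' Simulate a complete synthetic night
#'
#' Convenience wrapper: hypnogram then signal from one spec.
#'
#' @param spec a [night_spec()].
#' @return list with `recording`, `hypnogram`, `spec`.
#' @export
simulate_night <- function(spec = night_spec()) {
  h <- generate_hypnogram(spec)
  list(recording = synthesize_night(h, spec), hypnogram = h, spec = spec)
}
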