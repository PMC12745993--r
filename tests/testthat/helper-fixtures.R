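# Shared fixtures, all generated in code.

# sine-wave recording
sine_rec <- function(freq, amp = 50, dur_s = 60, fs = 100, phase = 0) {
  t <- seq_len(dur_s * fs) / fs
  eeg_recording(amp * sin(2 * pi * freq * t + phase), fs, "test")
}

# epoched signal straight from a matrix (rows = epochs)
epochs_from_matrix <- function(m, fs = 100) {
  structure(list(epochs = m, epoch_duration_s = ncol(m) / fs,
                 sampling_rate = fs),
            class = "epoched_signal")
}

# epoched signal from a list of per-epoch generator functions
epochs_from_gen <- function(n, gen, fs = 100, dur_s = 30) {
  m <- t(vapply(seq_len(n), function(i) gen(i), numeric(dur_s * fs)))
  epochs_from_matrix(m, fs)
}

# a spectral_decomposition built directly from an oscillatory matrix
# (fractal part zero), for feature tests that construct psd_osc by hand
dec_from_osc <- function(osc, freqs) {
  structure(list(psd_fra = matrix(0, nrow(osc), ncol(osc)),
                 psd_osc = osc, psd = osc, freqs = freqs,
                 resolution = freqs[2] - freqs[1], smoothed = TRUE),
            class = "spectral_decomposition")
}

pink_epoch <- function(rms = 12, alpha = 1.5, n = 3000, fs = 100) {
  aisleep:::pink_noise(n, alpha, rms, fs)
}

# one small synthetic night + staged result, computed once per test run
.night_cache <- new.env(parent = emptyenv())
small_night <- function(n_epochs = 120, seed = 5) {
  key <- sprintf("n%d_s%d", n_epochs, seed)
  if (is.null(.night_cache[[key]])) {
    spec <- night_spec(n_epochs = n_epochs, seed = seed)
    .night_cache[[key]] <- simulate_night(spec)
  }
  .night_cache[[key]]
}
staged_small_night <- function(n_epochs = 120, seed = 5) {
  key <- sprintf("res_n%d_s%d", n_epochs, seed)
  if (is.null(.night_cache[[key]])) {
    sim <- small_night(n_epochs, seed)
    .night_cache[[key]] <- suppressWarnings(run_aisleep(sim$recording))
  }
  .night_cache[[key]]
}
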