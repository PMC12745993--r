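#' EEG recording container
#'
#' @param samples numeric vector, microvolts.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param channel_label channel name, e.g. "Fpz-Cz".
#' @return an object of class `eeg_recording` with fields `samples`,
#'   `sampling_rate`, `channel_label`, `duration_s`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_label = "EEG") {
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("recording contains non-finite samples")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_label = as.character(channel_label),
         duration_s = length(samples) / sampling_rate),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> channel %s: %.1f s at %g Hz (%d samples)\n",
              x$channel_label, x$duration_s, x$sampling_rate,
              length(x$samples)))
  invisible(x)
}

# ---- EDF (European Data Format, 16-bit) -----------------------------------

edf_field <- function(con, n) {
  trimws(rawToChar(readBin(con, "raw", n)))
}

edf_pad <- function(x, n) {
  x <- substr(as.character(x), 1L, n)
  formatC(x, width = n, flag = "-")
}

read_edf_header <- function(con) {
  version <- edf_field(con, 8)
  patient <- edf_field(con, 80)
  recording <- edf_field(con, 80)
  startdate <- edf_field(con, 8)
  starttime <- edf_field(con, 8)
  header_bytes <- as.integer(edf_field(con, 8))
  reserved <- edf_field(con, 44)
  n_records <- as.integer(edf_field(con, 8))
  record_duration <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF file: bad signal count")
  fld <- function(w) vapply(seq_len(ns), function(i) edf_field(con, w), "")
  labels <- fld(16); transducer <- fld(80); phys_dim <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  prefilter <- fld(80); spr <- as.integer(fld(8)); fld(32)
  list(version = version, patient = patient, recording = recording,
       startdate = startdate, starttime = starttime,
       header_bytes = header_bytes, n_records = n_records,
       record_duration = record_duration, ns = ns, labels = labels,
       phys_dim = phys_dim, phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, spr = spr)
}

#' Read one channel of an EDF recording
#'
#' Reads a 16-bit EDF/EDF+ file, extracts the requested channel by label,
#' converts digital values to physical units and resamples to 100 Hz when
#' the stored rate differs (FFT-based, anti-aliased). Units are assumed to
#' be microvolts (millivolt-labelled channels are scaled by 1000).
#'
#' @param path EDF file path.
#' @param channel channel label; matching is exact after whitespace
#'   trimming.
#' @param target_rate resample target in Hz; the staging pipeline expects
#'   100 Hz. Set `NA` to keep the native rate.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, channel, target_rate = 100) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- tryCatch(read_edf_header(con),
                  error = function(e) stop("unreadable EDF file: ",
                                           conditionMessage(e)))
  idx <- match(channel, hdr$labels)
  if (is.na(idx)) {
    stop("channel '", channel, "' not found; available channels: ",
         paste(hdr$labels, collapse = ", "))
  }
  total_spr <- sum(hdr$spr)
  raw <- readBin(con, "integer", n = hdr$n_records * total_spr, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < hdr$n_records * total_spr) {
    stop("unreadable EDF file: truncated data section")
  }
  # per-record sample offsets of the requested signal
  offs <- c(0L, cumsum(hdr$spr))[idx]
  take <- as.vector(outer(offs + seq_len(hdr$spr[idx]),
                          (seq_len(hdr$n_records) - 1L) * total_spr, "+"))
  dig <- raw[take]
  scale <- (hdr$phys_max[idx] - hdr$phys_min[idx]) /
    (hdr$dig_max[idx] - hdr$dig_min[idx])
  x <- (dig - hdr$dig_min[idx]) * scale + hdr$phys_min[idx]
  if (grepl("^mV$", hdr$phys_dim[idx], ignore.case = TRUE)) x <- x * 1000
  fs <- hdr$spr[idx] / hdr$record_duration
  if (!is.na(target_rate) && abs(fs - target_rate) > 1e-9) {
    n_out <- round(length(x) * target_rate / fs)
    x <- fft_resample(x, n_out)
    fs <- target_rate
  }
  eeg_recording(x, fs, hdr$labels[idx])
}

#' Write a recording to a 16-bit EDF file
#'
#' One data record per second. The physical range is the symmetric range
#' just covering the signal, so round-trip quantization error is bounded by
#' `range/2^15`. Recordings whose duration is not a whole number of seconds
#' are zero-padded to the next second with a warning.
#'
#' @param rec an [eeg_recording()] with an integer sampling rate.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer Hz")
  fs <- as.integer(round(fs))
  x <- rec$samples
  n_rec <- ceiling(length(x) / fs)
  if (n_rec * fs != length(x)) {
    warning("recording padded with zeros to a whole number of seconds")
    x <- c(x, numeric(n_rec * fs - length(x)))
  }
  pmax_ <- max(1, max(abs(x)))
  pmin_ <- -pmax_
  dmin <- -32768; dmax <- 32767
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  dig <- as.integer(pmin(pmax(round((x - pmin_) / scale) + dmin, dmin),
                         dmax))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(edf_pad(s, w)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L + 256L), 8)   # header bytes: fixed + 1 signal
  wr("", 44); wr(as.character(n_rec), 8); wr("1", 8); wr("1", 4)
  wr(rec$channel_label, 16); wr("", 80); wr("uV", 8)
  wr(format(pmin_, nsmall = 0), 8); wr(format(pmax_, nsmall = 0), 8)
  wr(as.character(dmin), 8); wr(as.character(dmax), 8)
  wr("", 80); wr(as.character(fs), 8); wr("", 32)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

# ---- epoching -------------------------------------------------------------

#' Cut a recording into non-overlapping 30-s epochs
#'
#' The epoch grid is anchored at the first sample; a trailing partial epoch
#' is discarded.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_s epoch duration in seconds (30 by convention).
#' @return an `epoched_signal`: list with `epochs` (n_epochs x
#'   samples_per_epoch matrix), `epoch_duration_s`, `sampling_rate`.
#' @export
segment_epochs <- function(rec, epoch_s = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- rec$sampling_rate * epoch_s
  if (abs(spe - round(spe)) > 1e-9) {
    stop("sampling_rate * epoch_s must be an integer number of samples")
  }
  spe <- as.integer(round(spe))
  n_ep <- length(rec$samples) %/% spe
  if (n_ep < 1L) {
    stop("recording shorter than one epoch (", epoch_s, " s)")
  }
  m <- matrix(rec$samples[seq_len(n_ep * spe)], nrow = n_ep, ncol = spe,
              byrow = TRUE)
  structure(list(epochs = m, epoch_duration_s = epoch_s,
                 sampling_rate = rec$sampling_rate),
            class = "epoched_signal")
}

# ---- hypnograms -----------------------------------------------------------

stage_tokens <- c("W" = 0L, "N1" = 1L, "N2" = 2L, "N3" = 3L,
                  "REM" = 4L, "R" = 4L, "U" = 5L, "?" = 5L,
                  "0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L,
                  "5" = 5L)

#' Read a hypnogram from single-column text
#'
#' One stage token per line; recognized vocabulary is `W, N1, N2, N3, REM`
#' (and `R`, `U`/`?` for Unknown) or the integer codes `0..5`. Lines that
#' are empty or start with `#` are skipped. Legacy R&K tokens such as `S3`
#' are a parse error: merge them with [rk_to_aasm()] first.
#'
#' @param path text file.
#' @return integer vector of stage codes 0-5, class `hypnogram`.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- toupper(trimws(lines[keep]))
  codes <- stage_tokens[toks]
  if (anyNA(codes)) {
    bad <- which(keep)[which(is.na(codes))[1L]]
    stop("unknown stage token '", trimws(lines[bad]), "' at line ", bad)
  }
  hypnogram(unname(codes))
}

#' @rdname read_hypnogram
#' @param h integer stage codes in 0..5.
#' @export
write_hypnogram <- function(h, path) {
  h <- hypnogram(h)
  writeLines(as.character(as.integer(h)), path)
  invisible(path)
}

#' Validate a stage-code sequence
#'
#' @param stages integer codes: 0 Wake, 1 N1, 2 N2, 3 N3, 4 REM,
#'   5 Unknown.
#' @return the codes as an integer vector of class `hypnogram`.
#' @export
hypnogram <- function(stages) {
  s <- as.integer(stages)
  if (anyNA(s) || any(s < 0L | s > 5L)) {
    stop("stage codes must all be integers in 0..5")
  }
  structure(s, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = 0:5,
                      labels = c("W", "N1", "N2", "N3", "REM", "?")))
  cat("<hypnogram>", length(x), "epochs:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Merge legacy R&K tokens into AASM stages
#'
#' Maps `W, S1, S2, S3, S4, R/REM` to AASM codes with S3 and S4 merged into
#' N3; `MOVEMENT` and `UNKNOWN` frames become code 5 so evaluation can drop
#' them. Intended for preparing reference hypnograms only.
#'
#' @param tokens character vector of R&K stage tokens.
#' @return a [hypnogram()].
#' @export
rk_to_aasm <- function(tokens) {
  map <- c("W" = 0L, "S1" = 1L, "S2" = 2L, "S3" = 3L, "S4" = 3L,
           "R" = 4L, "REM" = 4L, "MOVEMENT" = 5L, "UNKNOWN" = 5L, "?" = 5L)
  codes <- map[toupper(trimws(tokens))]
  if (anyNA(codes)) {
    stop("unknown R&K token '", tokens[which(is.na(codes))[1L]], "'")
  }
  hypnogram(unname(codes))
}
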