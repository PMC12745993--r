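# The five-step staging cascade. Each step converts Unknown epochs (code 5)
# to a concrete stage by comparing feature-weighted kernel densities on the
# 2-D embedding; previously assigned labels are never overwritten, except
# for the explicit candidate reassignment in the N3 step.

# high-density selection rule. The printed algorithms carry "<" but the
# selected region is the one where density exceeds the fraction of the
# global maximum; `literal` reproduces the printed comparison.
density_select <- function(p, fraction, literal = FALSE) {
  if (literal) p < max(p) * fraction else p >= max(p) * fraction
}

new_stage_details <- function(...) list(...)

#' Stage the open-eye Wake state from gamma power
#'
#' An Otsu threshold splits the gamma-power distribution; KDE weights are 1
#' above the high-power mean, 0 below the threshold, and twice the
#' percentile rank (within the above-threshold subset) in between. Epochs
#' in the high-density region of the weighted KDE become Wake (0).
#'
#' @param emb an `embedding2d`.
#' @param gamma per-epoch gamma band power (dB).
#' @param S working hypnogram, all-Unknown at this point.
#' @param cfg configuration.
#' @return updated hypnogram with a `details` attribute (density `p`,
#'   threshold `th`, `mu_high`, weights `w`).
#' @export
stage_wake_open <- function(emb, gamma, S, cfg = ais_config()) {
  S <- hypnogram(S)
  th <- tryCatch(otsu_threshold(gamma, cfg$otsu$n_bins),
                 error = function(e) NULL)
  if (is.null(th) || !any(gamma > th)) {
    warning("degenerate gamma distribution; open-eye Wake step skipped")
    return(S)
  }
  above <- gamma > th
  mu_high <- mean(gamma[above])
  prank <- stats::ecdf(gamma[above])
  w <- ifelse(gamma > mu_high, 1,
              ifelse(gamma < th, 0, 2 * prank(gamma)))
  model <- wkde_model(emb$coords, w, cfg$kde$raw_bandwidth)
  p <- evaluate_density(model, emb$coords)
  if (max(p) <= 0) {
    warning("all-zero wake density; open-eye Wake step skipped")
    return(S)
  }
  sel <- density_select(p, cfg$staging$density_fraction,
                        cfg$staging$literal_sign)
  S[sel & unclass(S) == 5L] <- 0L
  attr(S, "details") <- new_stage_details(p_wake = p, th = th,
                                          mu_high = mu_high, w = w)
  S
}

#' Stage the spindle-rich N2N3 super-stage
#'
#' The personalized spindle power is split at zero; Gaussians fitted to
#' each side give cumulative-probability weights for two competing KDEs
#' (spindle vs. non-spindle). Unknown epochs where the spindle density
#' wins become the working N2N3 stage (code 2). When one side of the zero
#' split is empty the split falls back to the Otsu threshold of the
#' spindle power.
#'
#' @param emb an `embedding2d`.
#' @param dec smoothed `spectral_decomposition` (unused directly, kept for
#'   interface symmetry and future per-step reweighting).
#' @param band the `spindle_band`.
#' @param psp per-epoch personalized spindle power.
#' @param S working hypnogram after the open-eye Wake step.
#' @param cfg configuration.
#' @return updated hypnogram with density details attached.
#' @export
stage_n2n3 <- function(emb, dec, band, psp, S, cfg = ais_config()) {
  S <- hypnogram(S)
  split <- 0
  pos <- psp >= split
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    warning("one side of the zero split empty; ",
            "falling back to an Otsu split of the spindle power")
    split <- tryCatch(otsu_threshold(psp, cfg$otsu$n_bins),
                      error = function(e) NULL)
    if (is.null(split)) {
      warning("degenerate spindle power; N2N3 step skipped")
      return(S)
    }
    pos <- psp >= split
    if (sum(pos) < 2L || sum(!pos) < 2L) {
      warning("spindle-power split still degenerate; N2N3 step skipped")
      return(S)
    }
  }
  fit_hi <- gaussian_fit(psp[pos])
  fit_lo <- gaussian_fit(psp[!pos])
  w_n2n3 <- gaussian_cdf(psp, fit_hi)
  w_non <- 1 - gaussian_cdf(psp, fit_lo)
  p_n2n3 <- evaluate_density(wkde_model(emb$coords, w_n2n3,
                                        cfg$kde$raw_bandwidth), emb$coords)
  p_non <- evaluate_density(wkde_model(emb$coords, w_non,
                                       cfg$kde$raw_bandwidth), emb$coords)
  sel <- p_n2n3 > p_non & unclass(S) == 5L
  S[sel] <- 2L
  attr(S, "details") <- new_stage_details(p_n2n3 = p_n2n3, p_non = p_non,
                                          w_n2n3 = w_n2n3, w_non = w_non,
                                          split = split)
  S
}

dist_to_set <- function(x, set, method = "nearest") {
  if (nrow(set) == 0L) return(Inf)
  d2 <- colSums((t(set) - x)^2)
  switch(method,
         nearest = sqrt(min(d2)),
         median_pairwise = stats::median(sqrt(d2)),
         centroid = sqrt(sum((colMeans(set) - x)^2)),
         stop("unknown distance method: ", method))
}

#' Stage N3 from slow-oscillation coverage
#'
#' KDE weights are `max(SO% - floor, 0)` (floor 10%), zeroed for epochs
#' already labeled Wake and for artifact epochs. Epochs in the high-density
#' region are candidates; each is assigned N3 if its embedding point lies
#' nearer the N2N3 point set than the Wake point set, else Wake. Remaining
#' code-2 epochs are N2 from this point on.
#'
#' @param emb an `embedding2d`.
#' @param sopct per-epoch slow-oscillation coverage in `[0, 1]`.
#' @param S working hypnogram after the N2N3 step.
#' @param cfg configuration.
#' @param exclude optional logical vector of epochs whose SO weight is
#'   forced to zero (amplitude artifacts).
#' @return updated hypnogram with density details attached.
#' @export
stage_n3 <- function(emb, sopct, S, cfg = ais_config(), exclude = NULL) {
  S <- hypnogram(S)
  w <- pmax(sopct - cfg$staging$so_weight_floor, 0)
  w[unclass(S) == 0L] <- 0
  if (!is.null(exclude)) w[exclude] <- 0
  if (all(w == 0)) {
    warning("no slow-oscillation coverage above the floor; no N3 assigned")
    return(S)
  }
  p_n3 <- evaluate_density(wkde_model(emb$coords, w,
                                      cfg$kde$raw_bandwidth), emb$coords)
  candidates <- which(density_select(p_n3, cfg$staging$density_fraction,
                                     cfg$staging$literal_sign))
  method <- cfg$staging$distance
  for (i in candidates) {
    other <- seq_along(S) != i            # a point never measures itself
    set_n2n3 <- emb$coords[other & unclass(S) == 2L, , drop = FALSE]
    set_wake <- emb$coords[other & unclass(S) == 0L, , drop = FALSE]
    d_n2n3 <- dist_to_set(emb$coords[i, ], set_n2n3, method)
    d_wake <- dist_to_set(emb$coords[i, ], set_wake, method)
    S[i] <- if (d_n2n3 < d_wake) 3L else 0L
  }
  attr(S, "details") <- new_stage_details(p_n3 = p_n3, w_so = w,
                                          candidates = candidates)
  S
}

#' Stage the closed-eye Wake state from oscillatory strength
#'
#' Epochs are split at the overall standard deviation of the oscillatory
#' matrix; Gaussian fits on both sides give CDF weights for competing
#' "oscillatory" vs "non-oscillatory" KDEs. Unknown epochs where the
#' oscillatory density wins are closed-eye Wake: their 5-20 Hz power is
#' alpha, not spindles, because spindle-dominated epochs were already
#' claimed by the N2N3 step. Existing labels are never overwritten.
#'
#' @param emb an `embedding2d`.
#' @param dec smoothed `spectral_decomposition` (interface symmetry).
#' @param stdosc per-epoch oscillatory strength from [std_osc()], with its
#'   `std_overall` attribute.
#' @param S working hypnogram after the N3 step.
#' @param cfg configuration.
#' @return updated hypnogram with density details attached.
#' @export
stage_wake_close <- function(emb, dec, stdosc, S, cfg = ais_config()) {
  S <- hypnogram(S)
  overall <- attr(stdosc, "std_overall")
  if (is.null(overall)) stop("stdosc must carry the std_overall attribute")
  hi <- stdosc >= overall
  if (sum(hi) < 2L || sum(!hi) < 2L) {
    warning("degenerate oscillatory-strength split; ",
            "closed-eye Wake step skipped")
    return(S)
  }
  fit_hi <- gaussian_fit(stdosc[hi])
  fit_lo <- gaussian_fit(stdosc[!hi])
  w_osc <- gaussian_cdf(stdosc, fit_hi)
  w_non <- 1 - gaussian_cdf(stdosc, fit_lo)
  p_osc <- evaluate_density(wkde_model(emb$coords, w_osc,
                                       cfg$kde$raw_bandwidth), emb$coords)
  p_non <- evaluate_density(wkde_model(emb$coords, w_non,
                                       cfg$kde$raw_bandwidth), emb$coords)
  sel <- p_osc > p_non & unclass(S) == 5L
  S[sel] <- 0L
  attr(S, "details") <- new_stage_details(p_osc = p_osc, p_nonosc = p_non,
                                          w_osc = w_osc, w_non = w_non,
                                          std_overall = overall)
  S
}

# uniform moving average with edge-replicated boundaries, output aligned
# to the input length (window extends floor((k-1)/2) left, the rest right)
smooth_stage_curve <- function(S, k) {
  n <- length(S)
  pl <- (k - 1L) %/% 2L
  pr <- k - 1L - pl
  padded <- c(rep(S[1L], pl), as.numeric(S), rep(S[n], pr))
  cs <- c(0, cumsum(padded))
  (cs[(k + 1L):(n + k)] - cs[1L:n]) / k
}

#' Resolve the remaining Unknown epochs into N1 and REM
#'
#' All Unknown epochs are provisionally REM. The stage-code sequence is
#' smoothed with a uniform kernel (default 20 epochs = 10 minutes); a REM
#' run shorter than 10 minutes is re-labeled N1 wherever the smoothed
#' curve sits closer to N1 than to REM, i.e. where
#' `(smoothed - 1) < (4 - smoothed)` (strict, so a tie stays REM). The
#' curve is re-smoothed after each modified run (or after each modified
#' epoch with `staging$resmooth = "epoch"`).
#'
#' @param S working hypnogram containing codes {0, 2, 3, 5}.
#' @param cfg configuration; `staging$kernel_size`,
#'   `staging$min_rem_epochs`.
#' @return a complete hypnogram with codes in 0..4 and the final smoothed
#'   curve in the `details` attribute.
#' @export
resolve_n1_rem <- function(S, cfg = ais_config()) {
  S <- unclass(hypnogram(S))
  k <- as.integer(cfg$staging$kernel_size)
  min_rem <- as.integer(cfg$staging$min_rem_epochs)
  per_epoch <- identical(cfg$staging$resmooth, "epoch")
  S[S == 5L] <- 4L
  sm <- smooth_stage_curve(S, k)
  r <- rle(S)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (r$values[j] != 4L || r$lengths[j] >= min_rem) next
    idx <- starts[j]:ends[j]
    if (per_epoch) {
      for (t in idx) {
        if ((sm[t] - 1) < (4 - sm[t])) {
          S[t] <- 1L
          sm <- smooth_stage_curve(S, k)
        }
      }
    } else {
      flip <- idx[(sm[idx] - 1) < (4 - sm[idx])]
      if (length(flip)) {
        S[flip] <- 1L
        sm <- smooth_stage_curve(S, k)
      }
    }
  }
  out <- hypnogram(S)
  attr(out, "details") <- new_stage_details(s_smoothed = sm)
  out
}

#' Run the full unsupervised staging pipeline
#'
#' Welch PSD, IRASA decomposition and smoothing, 2-D embedding, feature
#' extraction, then the five carving steps in order: open-eye Wake (gamma),
#' N2N3 (spindle power), N3 (slow oscillations), closed-eye Wake
#' (oscillatory strength), and the N1/REM temporal resolution. All
#' intermediates are returned for interpretability.
#'
#' @param rec an [eeg_recording()] at 100 Hz, at least 10 minutes long.
#' @param cfg configuration from [ais_config()] or [read_config()].
#' @param seed embedding seed; overrides `cfg$umap$seed` when given.
#' @param verbose print per-step epoch counts.
#' @return an `aisleep_result`: list with `hypnogram`, `densities` (per
#'   step), `features` (per-epoch table), `spindle_band`, `so_events`,
#'   `embedding`, `psd`, `decomposition`, `config`, `counts`.
#' @export
run_aisleep <- function(rec, cfg = ais_config(), seed = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$duration_s < 600) stop("recording shorter than 10 minutes")
  if (!is.null(seed)) cfg$umap$seed <- as.integer(seed)
  say <- function(...) if (verbose) message(sprintf(...))

  ep <- segment_epochs(rec)
  psd <- welch_psd_db(ep, cfg)
  dec <- irasa_decompose(ep, cfg = cfg)
  dec_s <- smooth_psd_osc(dec, cfg$smooth$sigma_time, cfg$smooth$sigma_freq)
  emb <- embed_psd(psd, cfg = cfg)

  gamma <- band_power(psd, cfg$staging$gamma_band)
  band <- personalized_spindle_band(dec_s, cfg)
  psp <- spindle_power(dec_s, band, cfg)
  events <- detect_slow_oscillations(rec, cfg)
  sopct <- so_percentage(events, ep)
  stdosc <- std_osc(dec_s, cfg)
  artifacts <- apply(abs(ep$epochs), 1L, max) > cfg$artifact$max_abs_uv

  n <- nrow(ep$epochs)
  S <- hypnogram(rep(5L, n))
  densities <- list()
  counts <- c(wake_open = 0L, n2n3 = 0L, n3 = 0L, wake_close = 0L,
              n1 = 0L, rem = 0L)

  S <- stage_wake_open(emb, gamma, S, cfg)
  densities$wake_open <- attr(S, "details")
  counts["wake_open"] <- sum(unclass(S) == 0L)
  say("open-eye Wake: %d epochs", counts["wake_open"])

  S <- stage_n2n3(emb, dec_s, band, psp, S, cfg)
  densities$n2n3 <- attr(S, "details")
  counts["n2n3"] <- sum(unclass(S) == 2L)
  say("N2N3: %d epochs", counts["n2n3"])

  S <- stage_n3(emb, sopct, S, cfg, exclude = artifacts)
  densities$n3 <- attr(S, "details")
  counts["n3"] <- sum(unclass(S) == 3L)
  say("N3: %d epochs (N2: %d)", counts["n3"], sum(unclass(S) == 2L))

  S <- stage_wake_close(emb, dec_s, stdosc, S, cfg)
  densities$wake_close <- attr(S, "details")
  counts["wake_close"] <- sum(unclass(S) == 0L) - counts["wake_open"]
  say("closed-eye Wake: %d additional epochs", counts["wake_close"])

  S <- resolve_n1_rem(S, cfg)
  densities$n1_rem <- attr(S, "details")
  counts["n1"] <- sum(unclass(S) == 1L)
  counts["rem"] <- sum(unclass(S) == 4L)
  say("N1: %d, REM: %d", counts["n1"], counts["rem"])

  attr(S, "details") <- NULL
  features <- data.frame(epoch = seq_len(n), gamma_power_db = gamma,
                         spindle_power_db = psp, so_percentage = sopct,
                         std_osc = as.numeric(stdosc),
                         artifact = artifacts)
  structure(list(hypnogram = S, densities = densities, features = features,
                 spindle_band = band, so_events = events, embedding = emb,
                 psd = psd, decomposition = dec_s, config = cfg,
                 counts = counts),
            class = "aisleep_result")
}

#' @export
print.aisleep_result <- function(x, ...) {
  cat("<aisleep_result>\n")
  print(x$hypnogram)
  cat(sprintf("  spindle band: %.2f-%.2f Hz; %d slow oscillations\n",
              x$spindle_band$low, x$spindle_band$high, nrow(x$so_events)))
  invisible(x)
}
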