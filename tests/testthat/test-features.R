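test_that("band_power averages strictly inside the band", {
  psd <- psd_matrix(matrix(10, 5, 251), seq(0, 50, by = 0.2))
  expect_equal(band_power(psd, c(25, 50)), rep(10, 5))
  expect_error(band_power(psd, c(50, 25)), "low < high")

  ep <- segment_epochs(sine_rec(30, amp = 40, dur_s = 60))
  p30 <- welch_psd_db(ep)
  expect_true(all(band_power(p30, c(25, 50)) > band_power(p30, c(1, 4))))

  # bins outside the band are irrelevant
  psd2 <- psd_matrix(matrix(rnorm(5 * 251), 5), seq(0, 50, by = 0.2))
  g1 <- band_power(psd2, c(10, 12))
  psd2$values[, psd2$freqs < 10 | psd2$freqs > 12] <- 99
  g2 <- band_power(psd2, c(10, 12))
  expect_equal(g1, g2)
})

# independent brute force: scan every interior bin edge, recompute the
# between-class variance from the histogram by direct summation
otsu_oracle <- function(values, n_bins = 256L) {
  edges <- seq(min(values), max(values), length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  best_bcv <- -Inf; best_edge <- NA_real_
  for (k in seq_len(n_bins - 1L)) {
    lo <- bin <= k; hi <- !lo
    if (!any(lo) || !any(hi)) next
    w0 <- mean(lo); w1 <- mean(hi)
    mu0 <- sum(mids[bin[lo]]) / sum(lo)
    mu1 <- sum(mids[bin[hi]]) / sum(hi)
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best_bcv + 1e-12) {
      best_bcv <- bcv; best_edge <- edges[k + 1L]
    }
  }
  best_edge
}

test_that("Otsu threshold: bimodal split, tie rule, degenerate input", {
  withr::with_seed(11, x <- c(rnorm(500, -5, 0.5), rnorm(500, 5, 0.5)))
  th <- otsu_threshold(x)
  # the variance is tied across the empty valley; ties resolve to the
  # lowest edge, which still separates the two clusters perfectly
  expect_true(all(x[1:500] < th) && all(x[501:1000] > th))
  expect_equal(th, otsu_oracle(x))

  th2 <- otsu_threshold(c(0, 0, 0, 10, 10, 10))
  expect_gt(th2, 0); expect_lt(th2, 10)
  expect_equal(th2, otsu_oracle(c(0, 0, 0, 10, 10, 10)))

  expect_error(otsu_threshold(rep(1, 5)), "degenerate")
})

test_that("Otsu equals the exhaustive maximizer on random instances", {
  withr::with_seed(12, {
    for (i in 1:50) {
      x <- c(rnorm(60, runif(1, -10, 0), runif(1, 0.2, 2)),
             rnorm(60, runif(1, 1, 10), runif(1, 0.2, 2)))
      expect_equal(otsu_threshold(x), otsu_oracle(x))
    }
  })
})

make_bump_osc <- function(peaks, freqs, height = 5, width = 0.8) {
  t(vapply(peaks, function(p) height * exp(-(freqs - p)^2 / (2 * width^2)),
           numeric(length(freqs))))
}

test_that("personalized spindle band follows the peak closest to 14 Hz", {
  freqs <- seq(0, 26, by = 0.2)
  osc14 <- make_bump_osc(rep(14, 30), freqs)
  b <- personalized_spindle_band(dec_from_osc(osc14, freqs))
  expect_equal(b$f_peak, 14, tolerance = 0.11)
  expect_equal(c(b$low, b$high), c(b$f_peak - 1, b$f_peak + 1))

  # bimodal: the mode at 10 Hz is larger but 14 Hz is closer to the target
  osc_bi <- make_bump_osc(c(rep(10, 60), rep(14, 40)), freqs)
  b2 <- personalized_spindle_band(dec_from_osc(osc_bi, freqs))
  expect_equal(b2$f_peak, 14, tolerance = 0.11)

  osc13 <- make_bump_osc(rep(13, 25), freqs)
  b3 <- personalized_spindle_band(dec_from_osc(osc13, freqs))
  expect_equal(c(b3$low, b3$high), c(12, 14), tolerance = 0.11)
})

test_that("no local maximum falls back to 14 Hz with a warning", {
  freqs <- seq(0, 26, by = 0.2)
  flat <- matrix(0, 25, length(freqs))
  flat[, 2] <- 1   # argmax pinned at the low edge for every epoch
  expect_warning(b <- personalized_spindle_band(dec_from_osc(flat, freqs)),
                 "no local maximum")
  expect_equal(b$f_peak, 14)
  expect_true(b$fallback)
})

test_that("spindle power honors its source and simple constructions", {
  freqs <- seq(0, 26, by = 0.2)
  osc <- matrix(0, 10, length(freqs))
  dec <- dec_from_osc(osc, freqs)
  band <- structure(list(f_peak = 14, low = 13, high = 15, fallback = FALSE),
                    class = "spindle_band")
  cfg_osc <- ais_config(psp = list(source = "psd_osc"))
  expect_equal(spindle_power(dec, band, cfg_osc), rep(0, 10))

  dec$psd_osc[, freqs > 13 & freqs < 15] <- 3
  expect_equal(spindle_power(dec, band, cfg_osc), rep(3, 10))

  # burst epochs rank above flat epochs through the real pipeline
  withr::with_seed(13, {
    ep <- epochs_from_gen(24, function(i) {
      x <- pink_epoch()
      if (i <= 12) {
        for (b in 1:5) x <- aisleep:::add_burst(x, 100, 14, 25,
                                                runif(1, 0.7, 1.5))
      }
      x
    })
  })
  dec_real <- smooth_psd_osc(irasa_decompose(ep), 0, 0.5)
  psp <- spindle_power(dec_real, band, ais_config())
  expect_gt(min(psp[1:12]), max(psp[13:24]))
})

test_that("slow-oscillation detector counts cycles and enforces criteria", {
  cyc <- sine_rec(0.9, amp = 80, dur_s = 60, phase = pi)  # 160 uV PTP
  ev <- detect_slow_oscillations(cyc)
  expect_gte(nrow(ev), floor(0.9 * 60) - 1)
  expect_lte(nrow(ev), ceiling(0.9 * 60) + 1)
  # every event re-satisfies the five criteria, re-measured independently
  expect_true(all(ev$ptp_uv > 75))
  expect_true(all(ev$neg_peak_uv < -10) && all(ev$pos_peak_uv > 10))
  expect_true(all(ev$neg_duration_s > 0.3 & ev$neg_duration_s < 1.5))
  expect_true(all(ev$pos_duration_s > 0.1 & ev$pos_duration_s < 1.0))
  expect_equal(ev$ptp_uv, ev$pos_peak_uv - ev$neg_peak_uv)

  expect_equal(nrow(detect_slow_oscillations(sine_rec(0.9, 35, 60))), 0L)
  expect_equal(nrow(detect_slow_oscillations(sine_rec(10, 25, 60))), 0L)
  expect_error(detect_slow_oscillations(sine_rec(1, 80, 3)), "4 s")
})

test_that("SO percentage splits events across epochs and conserves time", {
  ep <- epochs_from_matrix(matrix(0, 4, 3000))
  no_ev <- detect_slow_oscillations(sine_rec(10, 1, 150))
  expect_equal(so_percentage(no_ev, ep), rep(0, 4))

  ev <- data.frame(start_s = c(5, 28), end_s = c(20, 34))
  pct <- so_percentage(ev, ep)
  expect_equal(pct[1], 17 / 30)      # 15 s + 2 s of the straddling event
  expect_equal(pct[2], 4 / 30)       # remaining 4 s
  expect_equal(sum(pct) * 30, 15 + 6)
})

test_that("std_osc measures oscillatory strength with its overall scalar", {
  freqs <- seq(0, 26, by = 0.2)
  osc <- matrix(0, 6, length(freqs))
  osc[4:6, ] <- make_bump_osc(rep(14, 3), freqs)
  v <- std_osc(dec_from_osc(osc, freqs))
  expect_equal(v[1:3], rep(0, 3))
  expect_gt(min(v[4:6]), 1)
  expect_equal(attr(v, "std_overall"), sd(as.vector(osc)))
})
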