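test_that("Welch PSD peaks at the tone frequency and is flat for noise", {
  ep <- segment_epochs(sine_rec(10, amp = 30, dur_s = 90))
  psd <- welch_psd_db(ep)
  expect_equal(nrow(psd$values), 3L)
  peak <- psd$freqs[apply(psd$values, 1L, which.max)]
  expect_true(all(abs(peak - 10) <= psd$resolution / 2 + 1e-12))

  withr::with_seed(1, {
    epn <- epochs_from_gen(4, function(i) rnorm(3000))
  })
  psdn <- welch_psd_db(epn)
  sel <- psdn$freqs >= 1 & psdn$freqs <= 49
  expect_true(all(apply(psdn$values[, sel], 1L, sd) < 3))
})

test_that("unit-variance white noise integrates to about 1 uV^2", {
  withr::with_seed(2, {
    ep <- epochs_from_gen(6, function(i) rnorm(3000))
  })
  psd <- welch_psd_db(ep)
  total <- rowSums(10^(psd$values / 10)) * psd$resolution
  expect_true(all(abs(total - 1) < 0.2))
})

test_that("degenerate epochs hit the power floor, NaN names the epoch", {
  ep <- epochs_from_matrix(matrix(0, 2, 3000))
  psd <- welch_psd_db(ep)
  expect_true(all(is.finite(psd$values)))
  expect_equal(unique(as.vector(psd$values)), 10 * log10(1e-12))

  bad <- matrix(rnorm(3 * 3000), 3)
  bad[2, 17] <- NaN
  expect_error(welch_psd_db(epochs_from_matrix(bad)), "epoch 2")
})

test_that("frequency grid meets the coverage and spacing contract", {
  ep <- epochs_from_matrix(matrix(rnorm(3000), 1))
  psd <- welch_psd_db(ep)
  expect_lte(psd$resolution, 0.25)
  expect_lte(min(psd$freqs), 0.2)
  expect_gte(max(psd$freqs), 50)
  expect_false(is.unsorted(psd$freqs, strictly = TRUE))
})

test_that("fft_resample changes length, preserves a tone", {
  t <- (seq_len(2000) - 1) / 200
  x <- sin(2 * pi * 7 * t)
  y <- fft_resample(x, 1000)
  expect_length(y, 1000L)
  t2 <- (seq_len(1000) - 1) / 100   # resampling keeps the time origin
  expect_lt(max(abs(y - sin(2 * pi * 7 * t2))), 0.02)
})

test_that("IRASA reconstructs exactly and rejects bad factors", {
  withr::with_seed(3, {
    ep <- epochs_from_gen(4, function(i) pink_epoch())
  })
  dec <- irasa_decompose(ep)
  expect_lt(max(abs(dec$psd - dec$psd_fra - dec$psd_osc)), 1e-9)
  expect_error(irasa_decompose(ep, h_set = c(0.9, 1.1)), "exceed 1")
  # determinism
  dec2 <- irasa_decompose(ep)
  expect_identical(dec$psd_osc, dec2$psd_osc)
})

test_that("IRASA isolates an oscillation on a 1/f background", {
  withr::with_seed(4, {
    ep <- epochs_from_gen(20, function(i) {
      t <- seq_len(3000) / 100
      pink_epoch() + 8 * sin(2 * pi * 14 * t + runif(1, 0, 2 * pi))
    })
  })
  dec <- irasa_decompose(ep)
  m <- colMeans(dec$psd_osc)
  expect_lt(abs(dec$freqs[which.max(m)] - 14), 0.5)
})

test_that("2-D smoothing: constant invariance, mass conservation, oracle", {
  cm <- dec_from_osc(matrix(5, 30, 40), seq(0.2, 8, by = 0.2))
  expect_equal(smooth_psd_osc(cm, 1, 0.5)$psd_osc, cm$psd_osc)

  # single-bin impulse: compare against a direct dense convolution with
  # symmetric (reflective) boundary handling
  n_t <- 21L; n_f <- 25L
  freqs <- seq(0.2, 5, by = 0.2)
  imp <- matrix(0, n_t, n_f)
  imp[11L, 13L] <- 1
  dec <- dec_from_osc(imp, freqs)
  sm <- smooth_psd_osc(dec, 1, 0.5)$psd_osc
  expect_lt(abs(sum(sm) - 1), 1e-6)

  st <- 1; sf <- 0.5 / 0.2
  rt <- ceiling(4 * st); rf <- ceiling(4 * sf)
  gt <- dnorm(-rt:rt, sd = st); gt <- gt / sum(gt)
  gf <- dnorm(-rf:rf, sd = sf); gf <- gf / sum(gf)
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n); ifelse(j >= n, 2 * n - 1 - j, j) + 1
  }
  oracle <- matrix(0, n_t, n_f)
  for (a in seq_len(n_t)) for (b in seq_len(n_f)) {
    acc <- 0
    for (u in -rt:rt) for (v in -rf:rf) {
      acc <- acc + gt[u + rt + 1] * gf[v + rf + 1] *
        imp[refl(a + u, n_t), refl(b + v, n_f)]
    }
    oracle[a, b] <- acc
  }
  expect_equal(sm, oracle, tolerance = 1e-12)

  # sigma -> 0 limit is the identity
  noisy <- dec_from_osc(matrix(rnorm(30 * 25), 30), freqs)
  expect_equal(smooth_psd_osc(noisy, 1e-12, 1e-12)$psd_osc, noisy$psd_osc)
})
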