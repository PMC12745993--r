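# Unit tests of the carving steps on constructed embeddings (two or three
# Gaussian blobs with known membership), plus pipeline-level checks on a
# cached synthetic night.

blob_embedding <- function(centers, n_per, seed = 99, sd = 0.4) {
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
    }))
  })
  structure(list(coords = pts, seed = seed), class = "embedding2d")
}

test_that("wake_open labels the gamma cluster and skips degenerate gamma", {
  emb <- blob_embedding(rbind(c(0, 0), c(6, 0)), 60)
  truth <- rep(c(TRUE, FALSE), each = 60)
  withr::with_seed(1, gamma <- ifelse(truth, rnorm(120, 5, 0.7),
                                      rnorm(120, -5, 0.7)))
  S0 <- hypnogram(rep(5L, 120))
  S <- stage_wake_open(emb, gamma, S0, ais_config())
  expect_gte(mean(unclass(S)[truth] == 0L), 0.9)
  # high-gamma epochs that were labeled have higher mean gamma
  expect_gt(mean(gamma[unclass(S) == 0L]), mean(gamma[unclass(S) != 0L]))

  expect_warning(Sd <- stage_wake_open(emb, rep(1, 120), S0, ais_config()),
                 "degenerate")
  expect_true(all(unclass(Sd) == 5L))
})

test_that("n2n3 converts only Unknown epochs where spindle density wins", {
  emb <- blob_embedding(rbind(c(0, 0), c(6, 0), c(3, 5)), 50)
  withr::with_seed(2, {
    psp <- c(rnorm(50, 8, 1), rnorm(50, -4, 1), rnorm(50, -4, 1))
  })
  S0 <- hypnogram(c(rep(5L, 100), rep(0L, 50)))  # third blob already Wake
  S <- stage_n2n3(emb, NULL, NULL, psp, S0, ais_config())
  expect_gte(mean(unclass(S)[1:50] == 2L), 0.85)
  expect_true(all(unclass(S)[101:150] == 0L))    # no overwrite
  expect_gt(mean(psp[unclass(S) == 2L]), mean(psp[unclass(S) != 2L]))
})

test_that("n2n3 falls back when one side of the zero split is empty", {
  emb <- blob_embedding(rbind(c(0, 0), c(6, 0)), 40)
  withr::with_seed(3, psp <- c(rnorm(40, -2, 0.3), rnorm(40, -8, 0.3)))
  S0 <- hypnogram(rep(5L, 80))
  expect_warning(S <- stage_n2n3(emb, NULL, NULL, psp, S0, ais_config()),
                 "falling back")
  expect_gte(mean(unclass(S)[1:40] == 2L), 0.8)
})

test_that("n3 carving assigns SO-rich candidates by proximity", {
  # blobs far apart relative to the KDE bandwidth: N2 cluster, N3 cluster
  # (nearer N2), Wake cluster (far)
  emb <- blob_embedding(rbind(c(0, 0), c(14, 0), c(7, 14)), 40, sd = 1)
  S0 <- hypnogram(c(rep(2L, 80), rep(0L, 40)))
  sopct <- c(rep(0, 40), rep(0.5, 40), rep(0, 40))
  S <- stage_n3(emb, sopct, S0, ais_config())
  expect_gte(mean(unclass(S)[41:80] == 3L), 0.8)
  expect_true(all(unclass(S)[1:40] == 2L))
  expect_gt(mean(sopct[unclass(S) == 3L]), mean(sopct[unclass(S) != 3L]))

  expect_warning(S2 <- stage_n3(emb, rep(0, 120), S0, ais_config()),
                 "no slow-oscillation")
  expect_identical(unclass(S2), unclass(S0))
})

test_that("artifact epochs are excluded from the SO weighting", {
  emb <- blob_embedding(rbind(c(0, 0), c(8, 0)), 40)
  S0 <- hypnogram(rep(c(2L, 5L), each = 40))
  sopct <- c(rep(0, 40), rep(0.6, 40))
  excl <- c(rep(FALSE, 40), rep(TRUE, 40))
  expect_warning(S <- stage_n3(emb, sopct, S0, ais_config(), exclude = excl),
                 "no slow-oscillation")
  expect_false(any(unclass(S) == 3L))
})

test_that("wake_close only claims Unknown oscillatory epochs", {
  emb <- blob_embedding(rbind(c(0, 0), c(6, 0), c(3, 5)), 50)
  withr::with_seed(4, {
    stdosc <- c(rnorm(50, 3, 0.3), rnorm(50, 0.8, 0.2), rnorm(50, 3, 0.3))
  })
  attr(stdosc, "std_overall") <- 2
  # first blob: alpha-rich, Unknown; third: spindle-rich but already N2
  S0 <- hypnogram(c(rep(5L, 100), rep(2L, 50)))
  S <- stage_wake_close(emb, NULL, stdosc, S0, ais_config())
  expect_gte(mean(unclass(S)[1:50] == 0L), 0.8)
  expect_true(all(unclass(S)[101:150] == 2L))    # N2 stays N2
  expect_true(all(unclass(S)[51:100] == 5L))     # non-oscillatory untouched

  flat <- rep(1, 150); attr(flat, "std_overall") <- 5
  expect_warning(stage_wake_close(emb, NULL, flat, S0, ais_config()),
                 "degenerate")
})

test_that("N1/REM resolution follows duration and smoothed-distance rules", {
  cfg <- ais_config()
  # 2-min unknown run inside a long Wake block becomes N1
  S <- hypnogram(c(rep(0L, 30), rep(5L, 4), rep(0L, 30)))
  out <- resolve_n1_rem(S, cfg)
  sm <- attr(out, "details")$s_smoothed
  expect_true(all(unclass(out)[31:34] == 1L))
  expect_false(any(unclass(out) == 5L))

  # a 30-minute unknown block stays REM regardless of the inequality
  S2 <- hypnogram(c(rep(0L, 30), rep(5L, 60), rep(0L, 30)))
  out2 <- resolve_n1_rem(S2, cfg)
  expect_true(all(unclass(out2)[31:90] == 4L))

  # smoothed value exactly 2.5: strict inequality keeps REM
  cfg3 <- ais_config(staging = list(kernel_size = 4L))
  S3 <- hypnogram(c(2L, 2L, 2L, 5L, 0L, 5L, 3L, 3L, 3L, 3L))
  out3 <- resolve_n1_rem(S3, cfg3)
  sm3 <- attr(out3, "details")$s_smoothed
  expect_equal(sm3[4], 2.5)
  expect_equal(unclass(out3)[c(4, 6)], c(4L, 4L))
})

test_that("the smoothed curve matches a hand convolution at the edges", {
  S <- hypnogram(c(rep(0L, 30), rep(5L, 4), rep(0L, 30)))
  out <- resolve_n1_rem(S, ais_config())
  # before any flip, the provisional-REM curve at the run is 4*4/20 = 0.8
  prov <- c(rep(0, 30), rep(4, 4), rep(0, 30))
  k <- 20L; pl <- 9L; pr <- 10L
  padded <- c(rep(prov[1], pl), prov, rep(prov[64], pr))
  hand <- vapply(seq_len(64), function(t) mean(padded[t:(t + k - 1)]), 0)
  expect_equal(max(hand), 0.8)
  expect_true(all((hand[31:34] - 1) < (4 - hand[31:34])))
})

test_that("the full pipeline is complete, monotone and deterministic", {
  sim <- small_night()
  res <- staged_small_night()
  S <- unclass(res$hypnogram)
  expect_length(S, 120L)
  expect_true(all(S %in% 0:4))

  # determinism: a second run gives an identical hypnogram
  res2 <- suppressWarnings(run_aisleep(sim$recording))
  expect_identical(unclass(res2$hypnogram), S)

  # recovered quality on this small night: all key stages decently found
  sc <- score(confusion(sim$hypnogram, res$hypnogram))
  expect_gt(sc$accuracy, 0.7)
})

test_that("the literal printed comparison is available behind its flag", {
  emb <- blob_embedding(rbind(c(0, 0), c(6, 0)), 60)
  truth <- rep(c(TRUE, FALSE), each = 60)
  withr::with_seed(5, gamma <- ifelse(truth, rnorm(120, 5, 0.7),
                                      rnorm(120, -5, 0.7)))
  S0 <- hypnogram(rep(5L, 120))
  lit <- ais_config(staging = list(literal_sign = TRUE))
  S <- stage_wake_open(emb, gamma, S0, lit)
  # inverted rule selects the low-density region: the gamma cluster stays
  expect_lt(mean(unclass(S)[truth] == 0L), 0.5)
})

test_that("per-epoch re-smoothing is a valid alternative", {
  S <- hypnogram(c(rep(0L, 30), rep(5L, 4), rep(0L, 30)))
  cfg <- ais_config(staging = list(resmooth = "epoch"))
  out <- resolve_n1_rem(S, cfg)
  expect_false(any(unclass(out) == 5L))
  expect_true(all(unclass(out)[31:34] %in% c(1L, 4L)))
})

test_that("short recordings and config plumbing error out cleanly", {
  expect_error(run_aisleep(sine_rec(1, dur_s = 60)), "10 minutes")
})
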