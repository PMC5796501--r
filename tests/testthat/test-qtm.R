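# Magnitude quantization, apnea-candidate relabelling, transition matrix.

test_that("quantize_levels maps magnitudes to the three base levels", {
  zero <- audio_recording(rep(0, 8000 * 10), 8000)
  expect_true(all(quantize_levels(zero)$levels == "SILENCE"))

  # absolute thresholds on frames of known RMS
  rec <- audio_recording(c(rep(0, 8000), rep(0.1, 8000), rep(0.9, 8000)), 8000)
  lev <- quantize_levels(rec, silence_thresh = 0.01, high_thresh = 0.5,
                         absolute = TRUE)
  expect_equal(lev$levels, c("SILENCE", "LOW", "HIGH"))

  # quantile thresholds reproduce the requested proportions on a spread-out
  # magnitude distribution (quantile oracle)
  # a spread-out magnitude distribution whose low tail keeps the absolute
  # noise-floor guard (2x the 2nd percentile) below the requested quantile
  set.seed(21)
  mags <- stats::runif(200, 0.05, 1)
  rec2 <- audio_recording(rep(mags, each = 800) * rep(c(1, -1), 100 * 800), 800)
  lev2 <- quantize_levels(rec2, frame_seconds = 1, silence_thresh = 0.25,
                          high_thresh = 0.90)
  tab <- table(factor(lev2$levels, c("SILENCE", "LOW", "HIGH")))
  expect_lte(abs(tab[["SILENCE"]] - 50), 1)
  expect_lte(abs(tab[["HIGH"]] - 20), 1)

  expect_error(quantize_levels(audio_recording(1, 8000)), "shorter")
  expect_error(quantize_levels(zero, silence_thresh = 0.9, high_thresh = 0.1),
               "ordered")
})

test_that("apnea-candidate rule is exhaustive over run lengths 1-120 s", {
  for (len in 1:120) {
    lv <- c("LOW", rep("SILENCE", len), "LOW")
    out <- mark_apnea_candidates(levels_seq(lv))$levels
    expected <- if (len >= 20 && len <= 60) "APNEA" else "SILENCE"
    expect_true(all(out[2:(len + 1L)] == expected),
                info = paste("run length", len))
    expect_equal(out[c(1L, len + 2L)], c("LOW", "LOW"))
  }
})

test_that("apnea-candidate relabelling is idempotent and respects frames", {
  set.seed(8)
  lv <- sample(c("SILENCE", "LOW", "HIGH"), 500, replace = TRUE,
               prob = c(0.5, 0.3, 0.2))
  once <- mark_apnea_candidates(levels_seq(lv))
  twice <- mark_apnea_candidates(once)
  expect_identical(once$levels, twice$levels)

  # duration measured via frame_seconds: 10 frames x 2.5 s = 25 s -> APNEA
  lv2 <- c("LOW", rep("SILENCE", 10), "LOW")
  out <- mark_apnea_candidates(levels_seq(lv2, frame_seconds = 2.5))$levels
  expect_true(all(out[2:11] == "APNEA"))
})

test_that("transition matrix equals the brute-force counting oracle", {
  # trivial cases
  q1 <- transition_matrix(levels_seq(rep("LOW", 10)))
  expect_equal(unname(q1$Q["LOW", ]), c(0, 1, 0, 0))
  expect_true(all(q1$zero_rows[c("SILENCE", "HIGH", "APNEA")]))
  q2 <- transition_matrix(levels_seq(c("LOW", "HIGH", "LOW", "HIGH", "LOW")))
  expect_equal(unname(q2$Q["LOW", "HIGH"]), 1)
  expect_equal(unname(q2$Q["HIGH", "LOW"]), 1)

  # seeded random sequences match independent pair counting exactly
  set.seed(33)
  for (rep_i in 1:5) {
    lv <- sample(c("SILENCE", "LOW", "HIGH", "APNEA"), 1000, replace = TRUE)
    mine <- transition_matrix(levels_seq(lv))
    oracle <- brute_force_qtm(lv)
    expect_identical(unname(mine$counts), unname(oracle$counts))
    expect_equal(unname(mine$Q), unname(oracle$Q))
    occupied <- rowSums(mine$counts) > 0
    expect_true(all(abs(rowSums(mine$Q[occupied, , drop = FALSE]) - 1) < 1e-9))
  }
  expect_error(transition_matrix(levels_seq("LOW")), "at least 2")
})

test_that("qtm_features flattens row-major with the documented names", {
  lv <- c(rep("SILENCE", 5), rep("LOW", 5))
  q <- transition_matrix(levels_seq(lv))
  f <- qtm_features(q)
  expect_named(f, qtm_feature_names())
  expect_equal(unname(f["qtm_SILENCE_SILENCE"]), 4 / 5)
  expect_equal(unname(f["qtm_SILENCE_LOW"]), 1 / 5)
  expect_equal(unname(f["qtm_LOW_LOW"]), 1)
  expect_true(all(f[grepl("^qtm_(HIGH|APNEA)", names(f))] == 0))

  # all-silence night
  qs <- transition_matrix(levels_seq(rep("SILENCE", 50)))
  fs <- qtm_features(qs)
  expect_equal(unname(fs["qtm_SILENCE_SILENCE"]), 1)
  expect_equal(sum(fs), 1)

  # occupancy fractions from counts
  occ <- qtm_occupancy(q)
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ["LOW"]), 4 / 9)
})
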