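# Spectral subtraction and stage filtering.

test_that("hypnogram parsing accepts synonyms and detects headers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("epoch_index\tstage", "0\t2", "1\tn3", "2\tW", "3\trem"), path)
  hyp <- read_hypnogram(path)
  expect_equal(hyp$stages, c("N2", "N3", "W", "REM"))
  writeLines(c("0\tN2", "1\tN1"), path)   # headerless
  expect_equal(read_hypnogram(path)$stages, c("N2", "N1"))
  expect_error(hypnogram(c("N2", "XX")), "unknown stage")
})

test_that("noise profile averages the quietest frames", {
  silent <- audio_recording(rep(0, 16000), 8000)
  expect_true(all(estimate_noise_profile(silent)$magnitude == 0))

  # white noise: per-bin profile approaches a flat level; Monte-Carlo
  # oracle over 20 repetitions at 10 s
  set.seed(42)
  profs <- replicate(20, {
    estimate_noise_profile(audio_recording(stats::rnorm(80000, sd = 0.1), 8000),
                           frac_quietest = 1)$magnitude
  })
  m <- rowMeans(profs)
  inner <- m[3:(length(m) - 2L)]   # edge bins carry half-width energy
  expect_lt(max(abs(inner - mean(inner)) / mean(inner)), 0.10)

  # a loud click is excluded by quiet-frame selection
  base <- rep(0, 80000)
  click <- base; click[40000:40800] <- 0.9
  p_silence <- estimate_noise_profile(audio_recording(base + 1e-6, 8000), 0.2)
  p_click <- estimate_noise_profile(audio_recording(click + 1e-6, 8000), 0.2)
  expect_equal(p_click$magnitude, p_silence$magnitude, tolerance = 1e-6)

  expect_error(estimate_noise_profile(audio_recording(rep(0.1, 10), 8000)),
               "shorter")
})

test_that("spectral subtraction: identity, SNR gain, noise suppression", {
  set.seed(7)
  clean <- tone(440, 10, amp = 0.3)
  noise <- stats::rnorm(80000, sd = 0.05)
  rec <- audio_recording(clean + noise, 8000)
  prof <- estimate_noise_profile(audio_recording(noise, 8000))

  # zero profile -> STFT round trip within 1e-6 RMS
  zero <- prof; zero$magnitude[] <- 0
  out0 <- spectral_subtract(rec, zero, floor = 0)
  expect_lt(sqrt(mean((out0$samples - rec$samples)^2)), 1e-6)

  # denoising strictly improves SNR
  den <- spectral_subtract(rec, prof)
  expect_gt(snr_db(clean, den$samples), snr_db(clean, rec$samples))
  expect_length(den$samples, length(rec$samples))

  # pure noise matching the profile is strongly suppressed (oversubtraction
  # 2 clears the magnitude fluctuation above the mean-magnitude profile)
  recn <- audio_recording(noise, 8000)
  denn <- spectral_subtract(recn, prof, oversubtraction = 2, floor = 0)
  expect_lt(sqrt(mean(denn$samples^2)), 0.2 * sqrt(mean(noise^2)))

  # energy never increases for oversubtraction >= 1, floor <= 1
  expect_lte(sum(den$samples^2), sum(rec$samples^2))

  # mismatched FFT configuration is an error
  expect_error(spectral_subtract(rec, prof, frame_ms = 64), "mismatch")
})

test_that("stage filter keeps the requested epochs in order", {
  rate <- 1000
  rec <- audio_recording(seq_len(120 * rate) / (120 * rate), rate)
  hyp <- hypnogram(c("W", "N2", "N3", "REM"), 30)
  out <- stage_filter(rec, hyp)
  expect_length(out$samples, 60 * rate)
  expect_identical(out$samples, rec$samples[(30 * rate + 1):(90 * rate)])

  # all epochs kept -> identity
  hyp_all <- hypnogram(rep("N2", 4), 30)
  expect_identical(stage_filter(rec, hyp_all)$samples, rec$samples)

  # duration property: epoch_seconds x kept epochs, truncated at the end
  rec2 <- audio_recording(stats::rnorm(100 * rate), rate)
  hyp2 <- hypnogram(c("N2", "W", "N2", "N3"), 30)   # 4th epoch truncated
  expect_length(stage_filter(rec2, hyp2)$samples, (30 + 30 + 10) * rate)

  # degenerate and error paths
  expect_warning(empty <- stage_filter(rec, hypnogram(rep("W", 4), 30)),
                 "no epoch")
  expect_true(isTRUE(attr(empty, "empty")))
  expect_error(stage_filter(rec, hypnogram(c("N2", "N2"), 30)), "cover")
  expect_error(stage_filter(rec, hyp, keep = character(0)), "empty keep")
  expect_warning(same <- stage_filter(rec, NULL), "skipped")
  expect_identical(same$samples, rec$samples)
})
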