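# Per-window features, formants, sub-bands, SPLs, aggregation, schema.

test_that("zero windows yield finite floor-valued features", {
  fr <- extract_window_features(numeric(40000), 8000)
  expect_true(all(is.finite(fr)))
  expect_equal(unname(fr["RMS"]), 0)
  expect_equal(unname(fr["ZC"]), 0)
  expect_equal(unname(fr["FLEW"]), 0)
  # MFCCs collapse to the DCT of a constant log-floor vector: all
  # coefficients above the zeroth vanish
  expect_true(all(abs(fr[paste0("MFCC_", 1:12)]) < 1e-8))
})

test_that("tones recover analytic ZC, peak frequency and centroid", {
  fr <- extract_window_features(tone(1000), 8000)
  expect_lte(abs(fr["ZC"] - 2 * 1000 * 5), 1)   # +-1 crossing
  bin_hz <- 8000 / 256
  expect_lt(abs(fr["SF_FFT"] - 1000), bin_hz + 1e-9)
  expect_lt(abs(fr["SF_ZC"] - 1000), 1)

  # equal-magnitude two-tone signal: centroid at the midpoint +- one bin
  two <- tone(800) + tone(1600)
  fr2 <- extract_window_features(two, 8000)
  expect_lt(abs(fr2["SC"] - 1200), bin_hz + 1e-9)
})

test_that("amplitude scaling acts as expected on each feature family", {
  set.seed(3)
  w <- stats::rnorm(40000) * 0.05 + tone(300, amp = 0.2)
  f1 <- extract_window_features(w, 8000)
  g <- 3.5
  f2 <- extract_window_features(g * w, 8000)
  expect_equal(unname(f2["RMS"]), unname(g * f1["RMS"]), tolerance = 1e-9)
  for (nm in c("ZC", "FLEW", "SC", "SR"))
    expect_equal(unname(f2[nm]), unname(f1[nm]), tolerance = 1e-9)
  for (nm in c("dBA", "dBC", "dB", "peak_dB"))
    expect_equal(unname(f2[nm] - f1[nm]), 20 * log10(g), tolerance = 1e-6)
})

test_that("formants recover planted resonances", {
  set.seed(11)
  n <- 40000; rate <- 8000
  mk_band <- function(fc, bw) {
    x <- stats::rnorm(n)
    X <- stats::fft(x)
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * rate / n
    X[abs(abs(f) - fc) > bw / 2] <- 0
    Re(stats::fft(X, inverse = TRUE)) / n
  }
  w <- 3 * mk_band(500, 300) + 2 * mk_band(1500, 300) + 1 * mk_band(2500, 300)
  out <- extract_formants(w, rate)
  freqs <- attr(out, "freqs")
  expect_lt(abs(freqs[1] - 500), 100)
  expect_lt(abs(freqs[2] - 1500), 100)
  expect_lt(abs(freqs[3] - 2500), 100)
  expect_true(out["F1"] > out["F2"] && out["F2"] > out["F3"])

  # pure tone: first envelope peak sits at the tone frequency
  ot <- extract_formants(tone(1000), rate)
  expect_lt(abs(attr(ot, "freqs")[1] - 1000), 100)

  # zero window: flagged, floor amplitudes
  oz <- extract_formants(numeric(1000), rate)
  expect_true(attr(oz, "flagged"))
  expect_true(all(oz == min(oz)))
})

test_that("gammatone sub-band energies localize and stay balanced", {
  expect_true(all(extract_subband_energies(numeric(4000), 8000) == 0))

  sb <- extract_subband_energies(tone(750), 8000)
  expect_gt(sb["sb2"], 5 * max(sb[-2]))

  # white noise: measured band ratio tracks the filterbank's analytic
  # band-gain ratio (flat input spectrum -> expected energy per band is the
  # row sum of the filterbank weights, grouped by band)
  W <- sdbscreen:::.gammatone_weights(129, 8000, 40L)
  band <- pmin(8L, 1L + floor(attr(W, "fc") / 500))
  expected <- tapply(rowSums(W), band, sum)
  set.seed(5)
  reps <- replicate(6, extract_subband_energies(stats::rnorm(40000), 8000))
  measured <- rowMeans(reps)
  expect_true(all(measured > 0))
  ratio <- (measured / sum(measured)) / (expected / sum(expected))
  expect_lt(max(abs(ratio - 1)), 0.2)
})

test_that("weighted SPLs match the IEC 61672 curves", {
  spl1k <- extract_weighted_spl(tone(1000), 8000)
  expect_lt(abs(spl1k["dBA"] - spl1k["dB"]), 0.2)   # 0 dB point of A curve
  spl100 <- extract_weighted_spl(tone(100), 8000)
  expect_lt(abs((spl100["dBA"] - spl100["dB"]) - (-19.1)), 0.5)
  # C weighting is near flat at both frequencies
  expect_lt(abs(spl1k["dBC"] - spl1k["dB"]), 0.2)
  expect_lt(abs(spl100["dBC"] - spl100["dB"]), 0.5)

  w <- tone(500, amp = 0.25)
  a <- extract_weighted_spl(w, 8000)
  b <- extract_weighted_spl(2 * w, 8000)
  for (nm in c("dBA", "dBC", "dB"))
    expect_equal(unname(b[nm] - a[nm]), 6.02, tolerance = 0.05)

  z <- extract_weighted_spl(numeric(100), 8000)
  expect_true(all(z == -120))
})

test_that("first_derivative follows the difference rule", {
  expect_equal(first_derivative(rep(4, 10)), rep(0, 9))
  expect_equal(first_derivative(seq(0, 18, by = 2)), rep(2, 9))
  expect_equal(first_derivative(c(1, 3, 2)), c(2, -1))
  expect_error(first_derivative(5), ">= 2")
})

test_that("aggregation computes the documented statistics", {
  schema <- feature_schema(include_qtm = FALSE)
  frames <- matrix(0, 4, length(sdbscreen:::.table1_features()) +
                     length(sdbscreen:::.extra_features()),
                   dimnames = list(NULL, c(sdbscreen:::.table1_features(),
                                           sdbscreen:::.extra_features())))
  frames[] <- 1.5
  agg <- aggregate_subject(frames)
  expect_named(agg, schema)
  expect_true(all(agg[grep("_sd$", names(agg))] == 0))
  expect_equal(unname(agg["RMS_mean"]), 1.5)
  expect_equal(unname(agg["F1_max"]), unname(agg["F1_min"]))

  # hand-arithmetic oracle on an RMS series
  frames[, "RMS"] <- c(1, 2, 3, 4)
  agg2 <- aggregate_subject(frames)
  expect_equal(unname(agg2["RMS_mean"]), 2.5)
  expect_equal(unname(agg2["RMS_sd"]), stats::sd(1:4))     # ~1.2910
  expect_equal(unname(agg2["RMS_d1_mean"]), 1)
  expect_equal(unname(agg2["RMS_d1_sd"]), 0)

  # permuting frames leaves raw-moment statistics unchanged
  perm <- frames[c(3, 1, 4, 2), ]
  agg3 <- aggregate_subject(perm)
  raw <- grep("_d1_", schema, invert = TRUE, value = TRUE)
  expect_equal(agg3[raw], agg2[raw])

  expect_error(aggregate_subject(frames[1, , drop = FALSE]), "2 window")
})

test_that("feature schema is locked and resolves the published fixture", {
  set.seed(9)
  f1 <- extract_window_features(stats::rnorm(20000), 8000)
  f2 <- extract_window_features(tone(500, 2.5), 8000)
  expect_identical(names(f1), names(f2))

  # every fixture entry maps to exactly one schema name
  fix <- load_discriminator_fixture()
  nm <- fixture_feature_names(fix)
  schema <- feature_schema()
  expect_true(all(nm %in% schema))
  expect_equal(anyDuplicated(schema), 0L)
})
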