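# Per-window audio features and their per-subject aggregation.
#
# Each 5-s analysis window yields one WindowFeatureFrame: a named numeric
# vector holding the general audio-feature bank (spectral shape, cepstra,
# LPC, moments, beat statistics), formant amplitudes, Gammatone sub-band
# energies and frequency-weighted sound pressure levels. Subject-level
# aggregation takes mean/SD of each bank feature and of its first
# derivative, and max/min/mean/SD of the formant/sub-band/SPL variables.
#
# Feature definitions follow the conventions of the jAudio feature
# extractor family; they are reimplemented from their published
# descriptions, not ported, and exact numeric agreement with any particular
# tool is a non-goal. Degenerate (all-zero) windows produce finite
# floor-valued features, never NaN, so aggregation is total.

.EPS_LOG <- 1e-10
.SPL_FLOOR_DB <- -120

# --- schema -----------------------------------------------------------------

.table1_features <- function(n_mfcc = 13L, lpc_order = 10L) {
  c("SC", "SR", "SF", "Compactness", "SV", "RMS", "FLEW", "ZC",
    "SB", "BS", "SSB", "SF_ZC", "SF_SC", "SF_FFT",
    paste0("MFCC_", 0:(n_mfcc - 1L)),
    paste0("CQMFCC_", 0:(n_mfcc - 1L)),
    paste0("LPC_", 0:(lpc_order - 1L)),
    paste0("MM_", 0:4),
    "RDF",
    paste0("AMoM_", 0:9),
    paste0("AMoM_MFCC_", 0:9),
    paste0("AMoM_CQMFCC_", 0:9),
    paste0("AMoM_LCQT_", 0:9))
}

.extra_features <- function() {
  c("F1", "F2", "F3", paste0("sb", 1:8),
    "dBA", "dBC", "dB", "peak_dBA", "peak_dBC", "peak_dB")
}

#' Names of all per-subject aggregated features
#'
#' The locked schema: identical for every subject and run. Bank features get
#' `_mean`/`_sd` of the raw per-window series and `_d1_mean`/`_d1_sd` of its
#' first derivative; formant, sub-band and SPL variables get
#' `_max`/`_min`/`_mean`/`_sd`; the 16 quantized-transition-matrix entries
#' are appended last (see [qtm_features()]).
#'
#' @param include_qtm append the 16 `qtm_*` names (default `TRUE`).
#' @return character vector of feature names, in canonical order.
#' @export
feature_schema <- function(include_qtm = TRUE) {
  t1 <- .table1_features()
  ex <- .extra_features()
  nm <- c(
    as.vector(t(outer(t1, c("_mean", "_sd"), paste0))),
    as.vector(t(outer(t1, c("_d1_mean", "_d1_sd"), paste0))),
    as.vector(t(outer(ex, c("_max", "_min", "_mean", "_sd"), paste0)))
  )
  if (include_qtm) nm <- c(nm, qtm_feature_names())
  nm
}

# --- small helpers ----------------------------------------------------------

.safe_div <- function(a, b) if (abs(b) < 1e-15) 0 else a / b

# normalised 2-D raw moments of a non-negative mass matrix; coordinates are
# scaled to [0,1] on both axes. Entry 1 is the total mass; entries 2..10 are
# the moments of orders (1,0),(0,1),(1,1),(2,0),(0,2),(2,1),(1,2),(3,0),(0,3).
.moments2d <- function(Mat) {
  tot <- sum(Mat)
  if (tot < 1e-15) return(numeric(10L))
  nr <- nrow(Mat); nc <- ncol(Mat)
  y <- if (nr > 1L) (seq_len(nr) - 1L) / (nr - 1L) else 0
  x <- if (nc > 1L) (seq_len(nc) - 1L) / (nc - 1L) else 0
  W <- Mat / tot
  ry <- rowSums(W); cx <- colSums(W)
  m10 <- sum(cx * x);  m01 <- sum(ry * y)
  m20 <- sum(cx * x^2); m02 <- sum(ry * y^2)
  m30 <- sum(cx * x^3); m03 <- sum(ry * y^3)
  xy <- as.numeric(y %*% W %*% x)
  m21 <- as.numeric(y %*% W %*% (x^2))
  m12 <- as.numeric((y^2) %*% W %*% x)
  c(tot, m10, m01, xy, m20, m02, m21, m12, m30, m03)
}

# average .moments2d over consecutive patches of `patch` columns
.patch_moments <- function(Mat, patch = 10L) {
  nc <- ncol(Mat)
  n_patch <- nc %/% patch
  if (n_patch == 0L) return(.moments2d(Mat))
  acc <- numeric(10L)
  for (j in seq_len(n_patch)) {
    cols <- ((j - 1L) * patch + 1L):(j * patch)
    acc <- acc + .moments2d(Mat[, cols, drop = FALSE])
  }
  acc / n_patch
}

# --- the per-window feature frame ------------------------------------------

#' Extract all per-window audio features
#'
#' Computes the full feature frame for one analysis window: the general
#' audio-feature bank, F1-F3 formant amplitudes, eight Gammatone sub-band
#' energies and A/C/linear-weighted sound pressure levels. Spectral features
#' use internal 32-ms Hann frames at 50% hop and are averaged over frames so
#' each window contributes a single value per feature.
#'
#' @param window numeric sample vector (one analysis window).
#' @param rate sampling rate in Hz.
#' @param frame_ms internal analysis frame (ms), default 32.
#' @param n_mfcc number of cepstral coefficients (default 13).
#' @param lpc_order linear-prediction order (default 10).
#' @param calibration_offset dB offset added to all SPLs (default 0:
#'   uncalibrated, dB re full scale).
#' @return named numeric vector (the window feature frame); every entry
#'   finite.
#' @export
extract_window_features <- function(window, rate, frame_ms = 32,
                                    n_mfcc = 13L, lpc_order = 10L,
                                    calibration_offset = 0) {
  stopifnot(length(window) > 0L, rate > 0)
  flen <- round(rate * frame_ms / 1000)
  hop <- flen %/% 2L
  dur <- length(window) / rate
  frames_raw <- .frame_signal(window, flen, hop)   # shared by all paths
  win_fn <- .hann(flen)
  frames_win <- frames_raw * win_fn
  S <- if (ncol(frames_win)) {
    stats::mvfft(frames_win)[seq_len(flen %/% 2L + 1L), , drop = FALSE]
  } else matrix(complex(0), flen %/% 2L + 1L, 0)
  M <- Mod(S)                         # n_bins x n_frames magnitude
  nb <- nrow(M); nf <- ncol(M)
  if (nf == 0L) { M <- matrix(0, nb, 1L); nf <- 1L }
  P <- M^2
  freqs <- .fft_freqs(flen, rate)
  colsumM <- colSums(M)
  colsumP <- colSums(P)

  out <- stats::setNames(numeric(length(.table1_features(n_mfcc, lpc_order))),
                         .table1_features(n_mfcc, lpc_order))

  # spectral centroid (Hz) per frame
  sc <- ifelse(colsumM > 1e-15, colSums(M * freqs) / colsumM, 0)
  out["SC"] <- mean(sc)
  # rolloff: 85% cumulative power point
  sr <- vapply(seq_len(nf), function(j) {
    if (colsumP[j] < 1e-30) return(0)
    freqs[which(cumsum(P[, j]) >= 0.85 * colsumP[j])[1L]]
  }, numeric(1))
  out["SR"] <- mean(sr)
  # spectral flux
  if (nf > 1L) out["SF"] <- mean(colSums((M[, -1L, drop = FALSE] -
                                            M[, -nf, drop = FALSE])^2))
  # compactness: irregularity of the log-magnitude spectrum
  logM <- log(M + .EPS_LOG)
  if (nb > 2L) {
    nbr <- (logM[1:(nb - 2L), , drop = FALSE] + logM[2:(nb - 1L), , drop = FALSE] +
              logM[3:nb, , drop = FALSE]) / 3
    out["Compactness"] <- mean(colSums(abs(logM[2:(nb - 1L), , drop = FALSE] - nbr)))
  }
  out["SV"] <- mean(sqrt(pmax(colMeans(M^2) - colMeans(M)^2, 0) * nb / (nb - 1L)))
  rms <- sqrt(mean(window^2))
  out["RMS"] <- rms
  # fraction of low-energy 100-ms sub-windows
  sub_len <- max(1L, round(rate * 0.1))
  n_sub <- length(window) %/% sub_len
  if (n_sub >= 1L) {
    sub_rms <- sqrt(colMeans(matrix(window[seq_len(n_sub * sub_len)]^2,
                                    nrow = sub_len)))
    out["FLEW"] <- mean(sub_rms < mean(sub_rms))
  }
  # zero crossings over the whole window
  sgn <- window >= 0
  zc <- sum(sgn[-1L] != sgn[-length(sgn)])
  out["ZC"] <- zc
  # beat histogram from the frame-RMS envelope autocorrelation
  env <- if (ncol(frames_raw)) sqrt(colMeans(frames_raw^2)) else numeric(0)
  if (length(env) > 4L) {
    e <- env - mean(env)
    hop_s <- hop / rate
    lag_lo <- max(1L, floor(0.3 / hop_s))          # 200 BPM
    lag_hi <- min(length(e) - 1L, ceiling(1.5 / hop_s))  # 40 BPM
    if (lag_hi > lag_lo) {
      ac <- vapply(lag_lo:lag_hi, function(l)
        sum(e[1:(length(e) - l)] * e[(l + 1L):length(e)]), numeric(1))
      bh <- pmax(ac, 0)
      if (any(bh > 0)) {
        best <- which.max(bh)
        out["SB"] <- 60 / ((lag_lo + best - 1L) * hop_s)   # BPM
        out["BS"] <- sum(bh)
        out["SSB"] <- max(bh)
      }
    }
  }
  out["SF_ZC"] <- zc / (2 * dur)
  out["SF_SC"] <- out["SC"]
  pmean <- rowMeans(P)
  if (sum(pmean) > 1e-30) out["SF_FFT"] <- freqs[which.max(pmean)]

  # MFCC: 26 mel filters -> log -> DCT
  melfb <- .cached(26L, nb, rate, fn = .mel_filterbank)
  dctM <- .cached(n_mfcc, 26L, fn = .dct_matrix)
  mel_log <- log(melfb %*% P + .EPS_LOG)
  mfcc <- dctM %*% mel_log                       # n_mfcc x nf
  out[paste0("MFCC_", 0:(n_mfcc - 1L))] <- rowMeans(mfcc)

  # constant-Q cepstra: log-frequency kernel -> log -> DCT
  K <- .cached(nb, rate, fn = .cq_kernel)
  cq <- K %*% M
  lcq <- log(cq + .EPS_LOG)
  dctC <- .cached(n_mfcc, nrow(K), fn = .dct_matrix)
  cqmfcc <- dctC %*% lcq
  out[paste0("CQMFCC_", 0:(n_mfcc - 1L))] <- rowMeans(cqmfcc)

  # LPC coefficients, frame-averaged; the mean autocorrelation is reused
  # for the formant envelope below
  ac_mean <- NULL
  if (ncol(frames_raw) > 0L) {
    R <- .frame_autocorr(frames_win, lpc_order)
    A <- .levinson(R, lpc_order)
    out[paste0("LPC_", 0:(lpc_order - 1L))] <- rowMeans(A)
    ac_mean <- rowMeans(R)
  }

  # method of moments over the mean magnitude spectrum (bin index axis)
  mmean <- rowMeans(M)
  tot <- sum(mmean)
  if (tot > 1e-15) {
    p <- mmean / tot
    idx <- seq_len(nb) - 1L
    mu <- sum(idx * p)
    out["MM_0"] <- tot
    out["MM_1"] <- mu
    out["MM_2"] <- sum((idx - mu)^2 * p)
    out["MM_3"] <- sum((idx - mu)^3 * p)
    out["MM_4"] <- sum((idx - mu)^4 * p)
  }
  # relative difference function: log of the frame-RMS derivative
  if (length(env) > 1L)
    out["RDF"] <- mean(log10(abs(diff(env)) + 1e-8))

  # area moments over 10-frame spectrogram / cepstrogram patches
  out[paste0("AMoM_", 0:9)] <- .patch_moments(M)
  out[paste0("AMoM_MFCC_", 0:9)] <- .patch_moments(abs(mfcc))
  out[paste0("AMoM_CQMFCC_", 0:9)] <- .patch_moments(abs(cqmfcc))
  out[paste0("AMoM_LCQT_", 0:9)] <- .patch_moments(lcq - log(.EPS_LOG))

  formants <- if (is.null(ac_mean) || ac_mean[1L] < 1e-20) {
    extract_formants(numeric(2L), rate)     # degenerate floor output
  } else .formants_from_autocorr(ac_mean, rate)
  c(out,
    formants,
    .subband_from_power(pmean, rate),        # reuse the window's spectrum
    extract_weighted_spl(window, rate, calibration_offset))
}

#' Formant amplitudes from the LPC spectral envelope
#'
#' Amplitudes (dB) of the first three local maxima, in ascending frequency,
#' of an order-10 LPC spectral envelope. Envelope peaks are used rather than
#' raw FFT peaks for robustness to spectral fine structure. When the
#' envelope has fewer than `n_peaks` maxima (flat spectra), missing entries
#' are filled with the envelope value at the upper band edge and the result
#' carries attribute `flagged = TRUE`.
#'
#' @param window numeric sample vector.
#' @param rate sampling rate (Hz).
#' @param n_peaks number of formants (default 3).
#' @param lpc_order LPC order of the envelope (default 10).
#' @return named numeric vector `F1..F3` (dB) with attributes `freqs` (Hz)
#'   and `flagged`.
#' @export
extract_formants <- function(window, rate, n_peaks = 3L, lpc_order = 10L) {
  stopifnot(length(window) > 0L)
  nm <- paste0("F", seq_len(n_peaks))
  if (all(window == 0)) {
    out <- stats::setNames(rep(.SPL_FLOOR_DB, n_peaks), nm)
    attr(out, "freqs") <- rep(NA_real_, n_peaks)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  w <- window * .hann(length(window))
  n <- length(w)
  ac <- vapply(0:lpc_order, function(k)
    sum(w[seq_len(n - k)] * w[(k + 1L):n]), numeric(1))
  .formants_from_autocorr(ac, rate, n_peaks, lpc_order)
}

# peak-pick the LPC envelope derived from an autocorrelation vector
.formants_from_autocorr <- function(ac, rate, n_peaks = 3L, lpc_order = 10L) {
  nm <- paste0("F", seq_len(n_peaks))
  A <- .levinson(matrix(ac, ncol = 1L), lpc_order)[, 1L]
  gain <- max(ac[1L] - sum(A * ac[2:(lpc_order + 1L)]), 1e-15)
  env <- .lpc_envelope_db(A, gain, rate)
  d <- diff(env$db)
  peaks <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  flagged <- length(peaks) < n_peaks
  amp <- freq <- numeric(n_peaks)
  for (i in seq_len(n_peaks)) {
    if (i <= length(peaks)) {
      amp[i] <- env$db[peaks[i]]; freq[i] <- env$freq[peaks[i]]
    } else {
      amp[i] <- env$db[length(env$db)]; freq[i] <- env$freq[length(env$freq)]
    }
  }
  out <- stats::setNames(amp, nm)
  attr(out, "freqs") <- freq
  attr(out, "flagged") <- flagged
  out
}

#' Gammatone sub-band energies
#'
#' Energy of the window after Gammatone filtering, summed into eight 500-Hz
#' sub-bands covering 0-4000 Hz (`sb1` = \[0,500) Hz, ..., `sb8` =
#' \[3500,4000) Hz). Filtering is applied in the frequency domain with the
#' squared magnitude response of a 4th-order Gammatone filterbank whose
#' centre frequencies are ERB-spaced; each channel's output energy is
#' assigned to the sub-band containing its centre frequency.
#'
#' @param window numeric sample vector.
#' @param rate sampling rate (Hz); with rate below 8000 Hz the sub-bands
#'   above Nyquist are reported as 0 with a warning.
#' @param n_channels number of Gammatone channels (default 40).
#' @return named numeric vector `sb1..sb8` (energies, >= 0).
#' @export
extract_subband_energies <- function(window, rate, n_channels = 40L) {
  stopifnot(length(window) > 0L)
  if (rate < 8000) warning("extract_subband_energies: rate < 8000 Hz; ",
                           "sub-bands above Nyquist are zero")
  flen <- min(length(window), round(rate * 0.032))
  st <- .stft(window, flen, max(1L, flen %/% 2L))
  Pmean <- if (ncol(st$S)) rowMeans(Mod(st$S)^2) else numeric(flen %/% 2L + 1L)
  .subband_from_power(Pmean, rate, n_channels)
}

.subband_from_power <- function(Pmean, rate, n_channels = 40L) {
  out <- stats::setNames(numeric(8L), paste0("sb", 1:8))
  if (length(Pmean) == 0L || sum(Pmean) == 0) return(out)
  W <- .cached(length(Pmean), rate, n_channels, fn = .gammatone_weights)
  ch_energy <- as.numeric(W %*% Pmean)
  band <- pmin(8L, 1L + floor(attr(W, "fc") / 500))
  for (k in 1:8) out[k] <- sum(ch_energy[band == k])
  out
}

#' Frequency-weighted sound pressure levels
#'
#' A-weighted (dBA), C-weighted (dBC) and unweighted (dB) RMS levels of the
#' window, plus the corresponding per-sample peak levels. Weighting applies
#' the IEC 61672 analytic response in the frequency domain (exact circular
#' filtering of the window); both curves are 0 dB at 1 kHz. Recordings are
#' uncalibrated, so levels are dB re full scale plus `calibration_offset`.
#'
#' @param window numeric sample vector.
#' @param rate sampling rate (Hz).
#' @param calibration_offset additive dB offset (default 0).
#' @param floor_db lower clamp for silent windows (default -120 dB).
#' @return named numeric vector `dBA, dBC, dB, peak_dBA, peak_dBC, peak_dB`.
#' @export
extract_weighted_spl <- function(window, rate, calibration_offset = 0,
                                 floor_db = .SPL_FLOOR_DB) {
  stopifnot(length(window) > 0L)
  n <- length(window)
  to_db <- function(v) {
    db <- ifelse(v > 0, 20 * log10(v), -Inf) + calibration_offset
    pmax(db, floor_db)
  }
  X <- stats::fft(window)
  f <- c(0:(n %/% 2L), -((n - n %/% 2L - 1L):1)) * rate / n
  f <- abs(f[seq_len(n)])
  wA <- .a_weight_lin(f); wA[1L] <- 0
  wC <- .c_weight_lin(f); wC[1L] <- 0
  xA <- Re(stats::fft(X * wA, inverse = TRUE)) / n
  xC <- Re(stats::fft(X * wC, inverse = TRUE)) / n
  c(dBA = to_db(sqrt(mean(xA^2))),
    dBC = to_db(sqrt(mean(xC^2))),
    dB = to_db(sqrt(mean(window^2))),
    peak_dBA = to_db(max(abs(xA))),
    peak_dBC = to_db(max(abs(xC))),
    peak_dB = to_db(max(abs(window))))
}

#' First difference of a per-window series
#'
#' `out[k] = series[k+1] - series[k]`; captures the temporal change of a
#' feature across consecutive windows.
#'
#' @param series numeric vector, length >= 2.
#' @return numeric vector of length `length(series) - 1`.
#' @export
first_derivative <- function(series) {
  if (length(series) < 2L) stop("first_derivative: series length must be >= 2")
  diff(series)
}

# --- aggregation ------------------------------------------------------------

#' Aggregate window feature frames to a subject feature vector
#'
#' Bank features: mean and sample SD (n-1 denominator) of the raw per-window
#' series and of its first derivative. Formant, sub-band and SPL variables:
#' max, min, mean and SD of the raw series. Names follow
#' `<feature>[_d1]_<stat>` and match [feature_schema()].
#'
#' @param frames list of window feature frames (from
#'   [extract_window_features()]) or a matrix with one row per window.
#' @return named numeric vector (without the qTM block).
#' @export
aggregate_subject <- function(frames) {
  if (is.list(frames)) frames <- do.call(rbind, frames)
  if (is.null(dim(frames)) || nrow(frames) < 2L)
    stop("aggregate_subject: need at least 2 window frames (SD undefined)")
  t1 <- intersect(.table1_features(), colnames(frames))
  ex <- intersect(.extra_features(), colnames(frames))
  out <- stats::setNames(numeric(length(feature_schema(include_qtm = FALSE))),
                         feature_schema(include_qtm = FALSE))
  for (f in t1) {
    v <- frames[, f]
    d <- diff(v)
    out[paste0(f, "_mean")] <- mean(v)
    out[paste0(f, "_sd")] <- stats::sd(v)
    out[paste0(f, "_d1_mean")] <- mean(d)
    out[paste0(f, "_d1_sd")] <- stats::sd(d)
  }
  for (f in ex) {
    v <- frames[, f]
    out[paste0(f, "_max")] <- max(v)
    out[paste0(f, "_min")] <- min(v)
    out[paste0(f, "_mean")] <- mean(v)
    out[paste0(f, "_sd")] <- stats::sd(v)
  }
  out
}

#' Full per-subject feature extraction
#'
#' Segments a (preprocessed) recording into windows, extracts every window
#' feature frame, aggregates to the subject level, and appends the 16
#' quantized-transition-matrix entries computed on the same recording.
#'
#' @param rec an [audio_recording()].
#' @param window_seconds analysis window (s), default 5.
#' @param config named list of overrides passed to the extractors
#'   (`frame_ms`, `n_mfcc`, `lpc_order`, `calibration_offset`) and to the
#'   qTM stage (`qtm_frame_s`, `silence_quantile`, `high_quantile`,
#'   `apnea_min_s`, `apnea_max_s`).
#' @return named numeric vector matching [feature_schema()].
#' @export
extract_subject_features <- function(rec, window_seconds = 5, config = list()) {
  cfg <- utils::modifyList(list(frame_ms = 32, n_mfcc = 13L, lpc_order = 10L,
                                calibration_offset = 0, qtm_frame_s = 1,
                                silence_quantile = 0.15, high_quantile = 0.85,
                                apnea_min_s = 20, apnea_max_s = 60), config)
  ws <- segment_windows(rec, window_seconds)
  if (length(ws$windows) < 2L)
    stop("extract_subject_features: recording too short (< 2 windows)")
  frames <- lapply(ws$windows, extract_window_features, rate = rec$rate,
                   frame_ms = cfg$frame_ms, n_mfcc = cfg$n_mfcc,
                   lpc_order = cfg$lpc_order,
                   calibration_offset = cfg$calibration_offset)
  vec <- aggregate_subject(frames)
  lev <- quantize_levels(rec, frame_seconds = cfg$qtm_frame_s,
                         silence_thresh = cfg$silence_quantile,
                         high_thresh = cfg$high_quantile)
  lev <- mark_apnea_candidates(lev, cfg$apnea_min_s, cfg$apnea_max_s)
  q <- transition_matrix(lev)
  c(vec, qtm_features(q))
}
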