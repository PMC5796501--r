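# Two-stage preprocessing: spectral-subtraction denoising followed by
# retention of stage-2/3 non-REM sleep. Overnight microphone recordings mix
# breathing with machine hum, duvet rustle and conversation; subtraction
# removes the stationary component and stage filtering drops the epochs in
# which most transient non-breathing noise occurs.

#' Construct a hypnogram
#'
#' Per-epoch sleep-stage labels aligned to a recording: epoch k (0-based)
#' covers the half-open interval `[k*epoch_seconds, (k+1)*epoch_seconds)`.
#'
#' @param stages character vector of stage labels in
#'   `{"W","N1","N2","N3","REM"}`.
#' @param epoch_seconds scoring epoch length (s); 30 s is the standard
#'   polysomnography epoch.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_seconds = 30) {
  stages <- .normalize_stages(stages)
  if (length(stages) == 0L) stop("hypnogram: stages must be non-empty")
  if (epoch_seconds <= 0) stop("hypnogram: epoch_seconds must be > 0")
  structure(list(stages = stages, epoch_seconds = epoch_seconds),
            class = "hypnogram")
}

.normalize_stages <- function(stages) {
  s <- toupper(trimws(as.character(stages)))
  s[s %in% c("2", "S2")] <- "N2"
  s[s %in% c("3", "S3", "4", "S4")] <- "N3"
  s[s %in% c("0", "WAKE")] <- "W"
  s[s %in% c("1", "S1")] <- "N1"
  s[s %in% c("R", "5")] <- "REM"
  bad <- setdiff(unique(s), c("W", "N1", "N2", "N3", "REM"))
  if (length(bad)) stop("hypnogram: unknown stage label(s): ",
                        paste(bad, collapse = ", "))
  s
}

#' Read a hypnogram TSV
#'
#' Two tab-separated columns, `epoch_index` and `stage`, no header required
#' (a header line is auto-detected). Stage labels are case-insensitive;
#' `"2"/"N2"` and `"3"/"N3"` are synonyms.
#'
#' @param path TSV path.
#' @param epoch_seconds epoch length (s).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_seconds = 30) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("stage", tolower(first))
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("read_hypnogram: expected 2 columns")
  names(df)[1:2] <- c("epoch_index", "stage")
  df <- df[order(as.integer(df$epoch_index)), ]
  hypnogram(df$stage, epoch_seconds)
}

#' Write a hypnogram TSV
#' @param hyp a [hypnogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  df <- data.frame(epoch_index = seq_along(hyp$stages) - 1L, stage = hyp$stages)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Estimate a stationary noise magnitude profile
#'
#' Per-frequency-bin noise magnitude, taken as the mean STFT magnitude over
#' the quietest fraction of frames (ranked by frame energy). Overnight
#' recordings have no guaranteed clean lead-in, but breathing is
#' intermittent, so the quietest frames are dominated by the stationary
#' background.
#'
#' @param rec an [audio_recording()].
#' @param frac_quietest fraction of lowest-energy frames to average
#'   (0 < frac <= 1); default 0.1.
#' @param frame_ms,hop_ms STFT frame and hop in milliseconds.
#' @return A `noise_profile`: per-bin linear magnitudes plus the STFT
#'   configuration used.
#' @export
estimate_noise_profile <- function(rec, frac_quietest = 0.1,
                                   frame_ms = 32, hop_ms = 16) {
  stopifnot(inherits(rec, "audio_recording"))
  if (frac_quietest <= 0 || frac_quietest > 1)
    stop("estimate_noise_profile: frac_quietest must be in (0, 1]")
  frame_len <- round(rec$rate * frame_ms / 1000)
  hop <- round(rec$rate * hop_ms / 1000)
  if (length(rec$samples) < frame_len)
    stop("estimate_noise_profile: recording shorter than one frame")
  st <- .stft(rec$samples, frame_len, hop)
  M <- Mod(st$S)
  energy <- colSums(M^2)
  k <- max(1L, floor(frac_quietest * ncol(M)))
  quiet <- order(energy)[seq_len(k)]
  prof <- rowMeans(M[, quiet, drop = FALSE])
  structure(list(magnitude = prof, frame_len = frame_len, hop = hop,
                 rate = rec$rate),
            class = "noise_profile")
}

#' Spectral subtraction denoising
#'
#' Boll-style magnitude subtraction: per STFT frame the output magnitude is
#' `max(|X| - oversubtraction * noise, floor * |X|)`, phase is reused, and
#' the signal is rebuilt by overlap-add with a COLA-compliant Hann window.
#' Total energy never increases when `oversubtraction >= 1` and
#' `floor <= 1`.
#'
#' @param rec an [audio_recording()].
#' @param noise a `noise_profile` from [estimate_noise_profile()]; its STFT
#'   configuration must match `frame_ms`/`hop_ms`.
#' @param oversubtraction multiplier on the noise magnitude (default 1).
#' @param floor spectral floor as a proportion of `|X|` (default 0.02),
#'   which suppresses musical-noise artifacts.
#' @param frame_ms,hop_ms STFT frame and hop in milliseconds.
#' @return A denoised [audio_recording()] of identical length and rate.
#' @export
spectral_subtract <- function(rec, noise, oversubtraction = 1, floor = 0.02,
                              frame_ms = 32, hop_ms = 16) {
  stopifnot(inherits(rec, "audio_recording"), inherits(noise, "noise_profile"))
  frame_len <- round(rec$rate * frame_ms / 1000)
  hop <- round(rec$rate * hop_ms / 1000)
  if (noise$frame_len != frame_len || noise$hop != hop)
    stop("spectral_subtract: noise profile FFT configuration mismatch")
  # pad by one frame per side: without this, modified frames at the edges
  # are divided by a near-zero window-weight sum and explode
  pad <- numeric(frame_len)
  x <- c(pad, rec$samples, pad)
  st <- .stft(x, frame_len, hop)
  M <- Mod(st$S)
  Mout <- pmax(M - oversubtraction * noise$magnitude, floor * M)
  scale <- Mout / pmax(M, 1e-300)   # Mout = 0 wherever M = 0
  y <- .istft(st$S * scale, frame_len, hop, length(x))
  y <- y[(frame_len + 1L):(frame_len + length(rec$samples))]
  audio_recording(y, rec$rate, rec$subject_id)
}

#' Keep only epochs in selected sleep stages
#'
#' Concatenates, in time order, the samples of epochs whose stage is in
#' `keep` (default N2 and N3: respiration there is stable and regular, and
#' the duvet/conversation noise of wake, N1 and REM is excluded). Removed
#' epochs are dropped, not muted, matching the reduced effective recording
#' length that downstream per-window statistics expect.
#'
#' @param rec an [audio_recording()].
#' @param hyp a [hypnogram()] covering at least the recording duration
#'   (excess epochs are ignored; a shortfall is an error). `NULL` skips
#'   filtering with a warning, for screening-only use without staging.
#' @param keep character vector of stages to retain.
#' @return The filtered [audio_recording()]; zero-length keeps raise a
#'   warning and return a single zero sample flagged via attribute `empty`.
#' @export
stage_filter <- function(rec, hyp, keep = c("N2", "N3")) {
  stopifnot(inherits(rec, "audio_recording"))
  if (is.null(hyp)) {
    warning("stage_filter: no hypnogram supplied; stage filtering skipped")
    return(rec)
  }
  stopifnot(inherits(hyp, "hypnogram"))
  if (length(keep) == 0L) stop("stage_filter: empty keep set")
  keep <- .normalize_stages(keep)
  n <- length(rec$samples)
  epoch_len <- round(hyp$epoch_seconds * rec$rate)
  n_epochs_needed <- ceiling(n / epoch_len)
  if (length(hyp$stages) < n_epochs_needed)
    stop("stage_filter: hypnogram (", length(hyp$stages),
         " epochs) does not cover recording (needs ", n_epochs_needed, ")")
  pieces <- list()
  for (k in seq_len(n_epochs_needed)) {
    if (hyp$stages[k] %in% keep) {
      a <- (k - 1L) * epoch_len + 1L
      b <- min(k * epoch_len, n)
      pieces[[length(pieces) + 1L]] <- rec$samples[a:b]
    }
  }
  if (length(pieces) == 0L) {
    warning("stage_filter: no epoch matches the keep set; empty recording")
    out <- audio_recording(0, rec$rate, rec$subject_id)
    attr(out, "empty") <- TRUE
    return(out)
  }
  audio_recording(unlist(pieces, use.names = FALSE), rec$rate, rec$subject_id)
}

#' Run the full preprocessing stage
#'
#' Spectral subtraction first, then stage filtering — in this order so the
#' noise estimate sees a contiguous signal and epoch joins introduce no
#' subtraction artifacts.
#'
#' @param rec an [audio_recording()].
#' @param hyp a [hypnogram()] or `NULL`.
#' @param config named list of overrides: `fft_ms`, `hop_ms`,
#'   `oversubtraction`, `floor`, `frac_quietest`, `keep_stages`.
#' @return The preprocessed [audio_recording()].
#' @export
preprocess_recording <- function(rec, hyp = NULL, config = list()) {
  cfg <- utils::modifyList(list(fft_ms = 32, hop_ms = 16, oversubtraction = 1,
                                floor = 0.02, frac_quietest = 0.1,
                                keep_stages = c("N2", "N3")), config)
  frame_len <- round(rec$rate * cfg$fft_ms / 1000)
  hop <- round(rec$rate * cfg$hop_ms / 1000)
  if (length(rec$samples) < frame_len)
    stop("preprocess_recording: recording shorter than one frame")
  den <- .spectral_subtract_chunked(rec, frame_len, hop, cfg$frac_quietest,
                                    cfg$oversubtraction, cfg$floor)
  stage_filter(den, hyp, cfg$keep_stages)
}

# Streaming spectral subtraction for overnight-scale signals. Identical in
# output to the one-shot route (same global quietest-fraction noise profile,
# same per-frame gains) but processed in ~60-s chunks with one-frame
# overlap-save at the joins, so peak allocation stays in the tens of MB
# instead of the signal's own footprint times several.
.spectral_subtract_chunked <- function(rec, frame_len, hop, frac_quietest,
                                       oversubtraction, floor_prop) {
  x <- rec$samples
  n <- length(x)
  win <- .hann(frame_len)
  n_bins <- frame_len %/% 2L + 1L
  chunk_frames <- 3750L                     # 60 s of 16-ms hops
  chunk_len <- chunk_frames * hop
  starts <- seq(1L, n, by = chunk_len)

  chunk_stft <- function(a) {
    # frames whose start lies in [a, a+chunk_len-1], with real neighbours
    # (or zeros at the signal edges) providing the trailing samples
    b <- min(a + chunk_len - 1L + (frame_len - hop), n)
    seg <- x[a:b]
    if (length(seg) < frame_len)
      seg <- c(seg, numeric(frame_len - length(seg)))
    .stft(seg, frame_len, hop)$S
  }

  # pass 1+2: global frame-energy threshold, then profile from quiet frames
  energies <- vector("list", length(starts))
  for (ci in seq_along(starts)) {
    S <- chunk_stft(starts[ci])
    energies[[ci]] <- colSums(Mod(S)^2)
  }
  energy <- unlist(energies, use.names = FALSE)
  k <- max(1L, floor(frac_quietest * length(energy)))
  thresh <- sort(energy)[k]
  prof_sum <- numeric(n_bins); prof_n <- 0L
  for (ci in seq_along(starts)) {
    S <- chunk_stft(starts[ci])
    quiet <- energies[[ci]] <= thresh
    if (any(quiet)) {
      prof_sum <- prof_sum + rowSums(Mod(S[, quiet, drop = FALSE]))
      prof_n <- prof_n + sum(quiet)
    }
  }
  prof <- prof_sum / max(prof_n, 1L)

  # pass 3: subtract and resynthesize chunk by chunk (overlap-save: each
  # chunk is extended by one frame on both sides and the interior kept)
  out <- numeric(n)
  for (ci in seq_along(starts)) {
    a <- starts[ci]
    b <- min(a + chunk_len - 1L, n)
    a_ext <- max(1L, a - frame_len)
    b_ext <- min(n, b + frame_len)
    seg <- c(numeric(frame_len - (a - a_ext)),
             x[a_ext:b_ext],
             numeric(frame_len - (b_ext - b)))
    st <- .stft(seg, frame_len, hop)
    M <- Mod(st$S)
    Mout <- pmax(M - oversubtraction * prof, floor_prop * M)
    y <- .istft(st$S * (Mout / pmax(M, 1e-300)), frame_len, hop, length(seg))
    out[a:b] <- y[(frame_len + 1L):(frame_len + (b - a + 1L))]
  }
  audio_recording(out, rec$rate, rec$subject_id)
}
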