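# Audio containers, WAV I/O, windowing, roster and hypnogram readers.

#' Construct an audio recording
#'
#' Container for a single-channel sound signal: a numeric sample vector with
#' its sampling rate and a subject identifier. Amplitudes are dimensionless
#' (nominal range \[-1, 1\]); overnight polysomnography microphones record
#' uncalibrated digital amplitude, so absolute levels only matter relative to
#' a configurable calibration offset (see [extract_weighted_spl()]).
#'
#' @param samples numeric vector of finite amplitudes, non-empty.
#' @param rate sampling rate in Hz (> 0).
#' @param subject_id subject label carried through the pipeline.
#' @return An object of class `audio_recording` with fields `samples`,
#'   `rate`, `subject_id`.
#' @export
audio_recording <- function(samples, rate, subject_id = "subject") {
  if (length(samples) == 0L) stop("audio_recording: samples must be non-empty")
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("audio_recording: samples must be finite numeric")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("audio_recording: rate must be a single positive number")
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         subject_id = as.character(subject_id)),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> subject=%s rate=%g Hz n=%d (%.1f s)\n",
              x$subject_id, x$rate, length(x$samples),
              length(x$samples) / x$rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `audio_recording`.
#' @return duration in seconds.
#' @export
duration_s <- function(rec) length(rec$samples) / rec$rate

# ---------------------------------------------------------------------------
# Minimal RIFF/WAVE codec. No audio package ships with this toolchain, and
# the format is simple: PCM 16/24/32-bit and IEEE float32 are supported.

.wav_read_header <- function(con) {
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L)
      stop("read_wav: no data chunk found")
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(raw_fmt[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("read_wav: data chunk precedes fmt chunk")
      return(c(fmt, list(data_bytes = sz)))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))  # skip unknown chunk
    }
  }
}

#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE audio: integer PCM (16/24/32-bit) or IEEE float32. Integer
#' samples are scaled to \[-1, 1\] by the conventional divisor `2^(bits-1)`.
#' Multichannel files are reduced to channel 0 (the first channel): the
#' bedside polysomnography microphone is mono, and extra channels carry no
#' breathing signal.
#'
#' @param path WAV file path.
#' @param subject_id label for the returned recording; default is the file
#'   name without extension.
#' @return An [audio_recording()].
#' @export
read_wav <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("read_wav: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .wav_read_header(con)
  if (!hdr$audio_format %in% c(1L, 3L))
    stop("read_wav: unsupported (compressed?) audio format tag ", hdr$audio_format)
  bytes_per <- hdr$bits %/% 8L
  n_total <- hdr$data_bytes %/% bytes_per
  if (n_total == 0L) stop("read_wav: zero-length audio")
  if (hdr$audio_format == 3L) {
    if (hdr$bits != 32L) stop("read_wav: only 32-bit float supported")
    x <- readBin(con, "double", n_total, 4, endian = "little")
  } else if (hdr$bits == 16L) {
    x <- readBin(con, "integer", n_total, 2, signed = TRUE, endian = "little") / 32768
  } else if (hdr$bits == 32L) {
    x <- readBin(con, "integer", n_total, 4, endian = "little") / 2147483648
  } else if (hdr$bits == 24L) {
    raw <- readBin(con, "raw", n_total * 3L)
    b <- matrix(as.integer(raw), nrow = 3L)
    v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else stop("read_wav: unsupported bit depth ", hdr$bits)
  if (hdr$n_channels > 1L)
    x <- x[seq(1L, length(x), by = hdr$n_channels)]
  if (is.null(subject_id))
    subject_id <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  audio_recording(x, hdr$sample_rate, subject_id)
}

#' Write a recording to a WAV file
#'
#' @param rec an [audio_recording()].
#' @param path output path.
#' @param bits 16 (integer PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bits = 16L) {
  stopifnot(inherits(rec, "audio_recording"), bits %in% c(16L, 32L))
  n <- length(rec$samples)
  bytes_per <- bits %/% 8L
  data_bytes <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 32L) 3L else 1L), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # mono
  writeBin(as.integer(round(rec$rate)), con, 4, endian = "little")
  writeBin(as.integer(round(rec$rate)) * bytes_per, con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, 4, endian = "little")
  if (bits == 32L) {
    writeBin(rec$samples, con, 4, endian = "little")
  } else {
    q <- as.integer(pmax(-32768, pmin(32767, round(rec$samples * 32768))))
    writeBin(q, con, 2, endian = "little")
  }
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Segment a recording into fixed-length analysis windows
#'
#' Splits the signal into contiguous, non-overlapping windows of
#' `window_seconds` each; a trailing partial window is discarded (not
#' zero-padded) so energy statistics are never diluted. An overnight
#' recording of 8 h at 5-s windows yields 5760 windows.
#'
#' @param rec an [audio_recording()].
#' @param window_seconds window length in seconds (> 0); 5 s is the default
#'   analysis scale, with 2.5/7.5/10 s as standard alternatives.
#' @return A `window_sequence`: list with `windows` (list of equal-length
#'   numeric vectors), `window_seconds`, and `rate`.
#' @export
segment_windows <- function(rec, window_seconds = 5) {
  stopifnot(inherits(rec, "audio_recording"))
  if (window_seconds <= 0) stop("segment_windows: window_seconds must be > 0")
  wlen <- round(window_seconds * rec$rate)
  n <- length(rec$samples)
  k <- n %/% wlen
  if (k == 0L) {
    warning("segment_windows: window longer than recording; no windows")
    windows <- list()
  } else {
    windows <- lapply(seq_len(k), function(i)
      rec$samples[((i - 1L) * wlen + 1L):(i * wlen)])
  }
  structure(list(windows = windows, window_seconds = window_seconds,
                 rate = rec$rate),
            class = "window_sequence")
}

#' @export
print.window_sequence <- function(x, ...) {
  cat(sprintf("<window_sequence> %d windows of %g s @ %g Hz\n",
              length(x$windows), x$window_seconds, x$rate))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Severity group from an AHI value
#'
#' Standard apnea-hypopnea index cut-offs: normal (AHI < 5),
#' mild (5 <= AHI < 15), moderate (15 <= AHI < 30), severe (AHI >= 30).
#'
#' @param ahi numeric vector of AHI values (events/hour, non-negative).
#' @return factor with levels `normal`, `mild`, `moderate`, `severe`.
#' @export
severity_from_ahi <- function(ahi) {
  if (any(ahi < 0)) stop("severity_from_ahi: AHI must be non-negative")
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = c("normal", "mild", "moderate", "severe"))
}

#' Severity group levels, in increasing severity order
#' @export
severity_levels <- function() c("normal", "mild", "moderate", "severe")

#' Read a subject roster CSV
#'
#' Expects a header `subject_id,ahi`. The severity group is derived from
#' AHI, never stored, so roster and grouping cannot disagree.
#'
#' @param path CSV path.
#' @return data.frame with `subject_id`, `ahi`, `severity_group`.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "ahi") %in% names(df)))
    stop("read_roster: need columns subject_id, ahi")
  df$ahi <- as.numeric(df$ahi)
  df$severity_group <- severity_from_ahi(df$ahi)
  df[, c("subject_id", "ahi", "severity_group")]
}

#' Write a subject roster CSV
#' @param roster data.frame with `subject_id` and `ahi`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(roster[, c("subject_id", "ahi")], path, row.names = FALSE)
  invisible(path)
}
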