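# Quantized transition matrix (qTM): the overnight magnitude envelope is
# quantized into four levels — silence, low, high, and apnea-candidate —
# and summarised by the 4x4 matrix of level-transition probabilities.
# Silences of 20-60 s are relabelled apnea candidates, following the
# clinical convention that breathing cessations of at least 20 s indicate
# obstructive apnea; shorter silences are quiet breathing and longer ones
# are treated as non-respiratory (microphone or position artifacts) and
# stay at the silence level.

.QTM_LEVELS <- c("SILENCE", "LOW", "HIGH", "APNEA")

#' Quantize a recording's magnitude envelope into three levels
#'
#' The recording is cut into non-overlapping frames of `frame_seconds`; each
#' frame's magnitude is its RMS. Frames at or below the silence threshold
#' become `SILENCE`, at or above the high threshold `HIGH`, otherwise `LOW`.
#' Thresholds given in (0,1) are treated as quantiles of the whole-night
#' frame-magnitude distribution (recordings are uncalibrated, so per-subject
#' adaptive thresholds are the default); values >= 1 or an attribute-free
#' absolute scale can be forced with `absolute = TRUE`.
#'
#' @param rec an [audio_recording()].
#' @param frame_seconds frame length (s), default 1: fine enough to resolve
#'   the 20-s apnea bound at 5% granularity while smoothing waveform
#'   oscillation.
#' @param silence_thresh silence cut (quantile by default), default 0.15.
#' @param high_thresh high cut (quantile by default), default 0.85.
#' @param absolute if `TRUE`, thresholds are absolute RMS magnitudes.
#' @return A `level_sequence`: list with `levels` (character vector over
#'   `SILENCE/LOW/HIGH/APNEA`) and `frame_seconds`.
#' @export
quantize_levels <- function(rec, frame_seconds = 1, silence_thresh = 0.15,
                            high_thresh = 0.85, absolute = FALSE) {
  stopifnot(inherits(rec, "audio_recording"))
  if (silence_thresh >= high_thresh)
    stop("quantize_levels: thresholds must be ordered silence < high")
  flen <- round(frame_seconds * rec$rate)
  n_frames <- length(rec$samples) %/% flen
  if (n_frames < 1L) stop("quantize_levels: recording shorter than one frame")
  mag <- sqrt(colMeans(matrix(rec$samples[seq_len(n_frames * flen)]^2,
                              nrow = flen)))
  if (absolute) {
    lo <- silence_thresh; hi <- high_thresh
  } else {
    # silence cut: the larger of the requested quantile and an absolute
    # noise-floor estimate (2x the 2nd-percentile frame magnitude). The
    # quantile alone misbehaves at the extremes: in high-AHI nights more
    # than the quantile's share of frames are genuinely silent and the cut
    # falls inside the silence cluster, fragmenting apnea-length runs,
    # while in quiet low-AHI nights it promotes breathing troughs to
    # silence. The noise-floor term anchors the cut just above the
    # stationary background instead.
    floor_est <- 2 * stats::quantile(mag, 0.02, names = FALSE)
    lo <- max(stats::quantile(mag, silence_thresh, names = FALSE), floor_est)
    hi <- max(stats::quantile(mag, high_thresh, names = FALSE), lo * 1.0001)
  }
  lev <- ifelse(mag <= lo, "SILENCE", ifelse(mag >= hi, "HIGH", "LOW"))
  structure(list(levels = lev, frame_seconds = frame_seconds),
            class = "level_sequence")
}

#' Relabel apnea-candidate silences
#'
#' Every maximal run of `SILENCE` frames whose duration lies in
#' `[min_s, max_s]` is relabelled `APNEA` in full; runs outside the range
#' are left unchanged. The operation is idempotent.
#'
#' @param seq a `level_sequence`.
#' @param min_s minimum candidate duration (s), default 20.
#' @param max_s maximum candidate duration (s), default 60.
#' @return The relabelled `level_sequence`.
#' @export
mark_apnea_candidates <- function(seq, min_s = 20, max_s = 60) {
  stopifnot(inherits(seq, "level_sequence"))
  if (min_s >= max_s) stop("mark_apnea_candidates: need min_s < max_s")
  r <- rle(seq$levels)
  dur <- r$lengths * seq$frame_seconds
  sel <- r$values == "SILENCE" & dur >= min_s & dur <= max_s
  r$values[sel] <- "APNEA"
  seq$levels <- inverse.rle(r)
  seq
}

#' Transition matrix over quantized levels
#'
#' Counts adjacent level pairs over the whole night and row-normalizes:
#' entry `q[m, n]` is the probability of moving from level `m` to level `n`
#' at the next frame. Level order is fixed as
#' `SILENCE, LOW, HIGH, APNEA`. Rows whose level never occurs are all-zero
#' and flagged in `zero_rows`.
#'
#' @param seq a `level_sequence` of length >= 2.
#' @return A `qtm` object: list with `Q` (4x4 row-stochastic matrix),
#'   `counts` (4x4 integer matrix) and `zero_rows` (logical, by level).
#' @export
transition_matrix <- function(seq) {
  stopifnot(inherits(seq, "level_sequence"))
  lv <- factor(seq$levels, levels = .QTM_LEVELS)
  n <- length(lv)
  if (n < 2L) stop("transition_matrix: need at least 2 frames")
  counts <- table(from = lv[-n], to = lv[-1L])
  counts <- matrix(as.integer(counts), 4L, 4L,
                   dimnames = list(from = .QTM_LEVELS, to = .QTM_LEVELS))
  rs <- rowSums(counts)
  Q <- counts / ifelse(rs > 0, rs, 1)
  Q[rs == 0, ] <- 0
  structure(list(Q = Q, counts = counts, zero_rows = rs == 0),
            class = "qtm")
}

#' @export
print.qtm <- function(x, ...) {
  cat("<qtm> transition probabilities (rows: from, cols: to)\n")
  print(round(x$Q, 3))
  invisible(x)
}

#' Names of the 16 flattened qTM entries
#' @return character vector `qtm_<from>_<to>` in row-major level order.
#' @export
qtm_feature_names <- function() {
  as.vector(t(outer(.QTM_LEVELS, .QTM_LEVELS,
                    function(a, b) paste0("qtm_", a, "_", b))))
}

#' Flatten a qTM into named subject features
#'
#' Row-major flattening of the 4x4 transition-probability matrix; rows with
#' no occupancy contribute zeros (kept sparse rather than uniform so absent
#' levels are informative).
#'
#' @param q a `qtm` from [transition_matrix()].
#' @return named numeric vector of 16 entries `qtm_<from>_<to>`.
#' @export
qtm_features <- function(q) {
  stopifnot(inherits(q, "qtm"))
  stats::setNames(as.vector(t(q$Q)), qtm_feature_names())
}

#' Level occupancy fractions of a qTM
#'
#' Fraction of frame transitions originating in each level (row counts over
#' total); the `APNEA` entry is the overnight apnea-candidate occupancy
#' that tracks a subject's respiratory-event burden.
#'
#' @param q a `qtm`.
#' @return named numeric vector over the four levels, summing to 1.
#' @export
qtm_occupancy <- function(q) {
  stopifnot(inherits(q, "qtm"))
  rs <- rowSums(q$counts)
  rs / sum(rs)
}

#' Serialize a qTM to JSON
#' @param q a `qtm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qtm_json <- function(q, path) {
  jsonlite::write_json(list(levels = .QTM_LEVELS, counts = q$counts,
                            probabilities = q$Q),
                       path, matrix = "rowmajor", digits = NA)
  invisible(path)
}
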