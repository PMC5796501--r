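# Shared fixture builders; everything generated in code, nothing on disk.

tone <- function(freq, dur_s = 5, rate = 8000, amp = 1) {
  amp * sin(2 * pi * freq * (0:(round(dur_s * rate) - 1L)) / rate)
}

snr_db <- function(clean, noisy) {
  10 * log10(sum(clean^2) / sum((noisy - clean)^2))
}

# a small 4-group feature table with optional planted group shifts
make_feature_table <- function(n_per_group = 30L, n_features = 20L, seed = 1L,
                               shifts = list()) {
  set.seed(seed)
  groups <- factor(rep(c("normal", "mild", "moderate", "severe"),
                       each = n_per_group),
                   levels = c("normal", "mild", "moderate", "severe"))
  X <- matrix(stats::rnorm(length(groups) * n_features), length(groups),
              n_features, dimnames = list(NULL, paste0("f", seq_len(n_features))))
  for (sh in shifts) {           # list(feature=, group=, delta=) or group="all"
    rows <- if (identical(sh$group, "all")) seq_along(groups)
            else which(groups == sh$group)
    X[rows, sh$feature] <- X[rows, sh$feature] + sh$delta
  }
  list(X = X, groups = groups)
}

# hand-built level sequence
levels_seq <- function(levels, frame_seconds = 1) {
  structure(list(levels = levels, frame_seconds = frame_seconds),
            class = "level_sequence")
}

# independent brute-force pair-counting oracle for transition matrices
brute_force_qtm <- function(levels) {
  lv <- c("SILENCE", "LOW", "HIGH", "APNEA")
  counts <- matrix(0L, 4, 4, dimnames = list(lv, lv))
  for (i in seq_len(length(levels) - 1L))
    counts[levels[i], levels[i + 1L]] <- counts[levels[i], levels[i + 1L]] + 1L
  rs <- rowSums(counts)
  Q <- counts / ifelse(rs > 0, rs, 1)
  Q[rs == 0, ] <- 0
  list(Q = Q, counts = counts)
}
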