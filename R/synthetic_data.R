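# Seeded synthetic overnight recordings with AHI-controlled structure.
#
# The generator states a simplified world: breathing is band-limited noise
# amplitude-modulated at the breathing period; snores are short harmonic
# stacks riding the inhale peaks, with a group-dependent gain; respiratory
# pauses are silence gaps whose hourly rate follows the subject's target
# AHI (a Poisson process) and whose durations are uniform on 10-60 s, so
# both the sub-20-s "stays silence" branch and the 20-60-s apnea-candidate
# branch are exercised; a stationary noise floor sits underneath. Its
# purpose is statistical structure for end-to-end testing, not acoustic
# realism — no airway physiology is modelled, and no attempt is made to
# match any clinical cohort's acoustic distributions.

#' Specification of one synthetic subject
#'
#' @param target_ahi planted respiratory-pause rate (events/hour, >= 0).
#' @param duration_s recording length (s); at least 10 breathing periods.
#' @param breathing_period_s breathing cycle (s), default 4.
#' @param snore_intensity relative snore gain (increases with severity in
#'   cohorts), default 0.15.
#' @param apnea_duration_range_s gap duration range (s), default `c(10, 60)`.
#' @param noise_floor background noise RMS, default 0.005.
#' @param rate sampling rate (Hz), default 8000.
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return a `synth_subject_spec` list.
#' @export
synth_subject_spec <- function(target_ahi, duration_s,
                               breathing_period_s = 4,
                               snore_intensity = 0.15,
                               apnea_duration_range_s = c(10, 60),
                               noise_floor = 0.005, rate = 8000,
                               seed = 1L) {
  if (target_ahi < 0) stop("synth_subject_spec: target_ahi must be >= 0")
  if (any(apnea_duration_range_s <= 0) ||
      apnea_duration_range_s[1L] >= apnea_duration_range_s[2L])
    stop("synth_subject_spec: invalid apnea duration range")
  if (duration_s < 10 * breathing_period_s)
    stop("synth_subject_spec: duration must cover >= 10 breathing periods")
  structure(list(target_ahi = target_ahi, duration_s = duration_s,
                 breathing_period_s = breathing_period_s,
                 snore_intensity = snore_intensity,
                 apnea_duration_range_s = apnea_duration_range_s,
                 noise_floor = noise_floor, rate = rate,
                 seed = as.integer(seed)),
            class = "synth_subject_spec")
}

# band-limit white noise to [lo, hi] Hz by FFT masking; long signals are
# produced in power-of-two chunks (a huge mixed-radix FFT is far slower,
# and chunk-boundary phase discontinuities are irrelevant for a noise
# carrier)
.bandlimited_noise <- function(n, rate, lo, hi) {
  chunk <- 2^20
  one_chunk <- function(m) {
    x <- stats::rnorm(m)
    X <- stats::fft(x)
    f <- c(0:(m %/% 2L), -((m - m %/% 2L - 1L):1)) * rate / m
    X[abs(f) < lo | abs(f) > hi] <- 0
    Re(stats::fft(X, inverse = TRUE)) / m
  }
  if (n <= chunk) {
    y <- one_chunk(n)
  } else {
    k <- n %/% chunk
    pieces <- vector("list", k + 1L)
    for (i in seq_len(k)) pieces[[i]] <- one_chunk(chunk)
    rem <- n - k * chunk
    if (rem > 0L) pieces[[k + 1L]] <- one_chunk(rem)
    y <- unlist(pieces, use.names = FALSE)
  }
  y / max(stats::sd(y), 1e-12)
}

#' Generate one synthetic overnight recording
#'
#' @param spec a [synth_subject_spec()].
#' @param subject_id label for the recording.
#' @return list with `rec` (an [audio_recording()]), `events` (data.frame
#'   of planted gaps: `start_s`, `duration_s`) and `snores` (count).
#' @export
synth_breathing_audio <- function(spec, subject_id = "synth") {
  stopifnot(inherits(spec, "synth_subject_spec"))
  set.seed(spec$seed)
  n <- round(spec$duration_s * spec$rate)
  t <- (seq_len(n) - 1L) / spec$rate

  # breathing: band-limited noise under a raised-cosine envelope
  carrier <- .bandlimited_noise(n, spec$rate, 300, 1200)
  env <- (0.5 - 0.5 * cos(2 * pi * t / spec$breathing_period_s))^2
  x <- 0.08 * carrier * env

  # snore bursts on inhale peaks, probability and gain scale with intensity
  n_cycles <- floor(spec$duration_s / spec$breathing_period_s)
  p_snore <- min(1, 0.25 + 1.2 * spec$snore_intensity)
  snore_at <- which(stats::runif(n_cycles) < p_snore)
  for (ci in snore_at) {
    f0 <- stats::runif(1, 80, 300)
    dur <- 0.8
    at <- round(((ci - 1L) + 0.25) * spec$breathing_period_s * spec$rate)
    len <- min(round(dur * spec$rate), n - at)
    if (len < spec$rate %/% 10L) next
    tt <- (seq_len(len) - 1L) / spec$rate
    stack <- rowSums(vapply(1:5, function(h)
      sin(2 * pi * h * f0 * tt + stats::runif(1, 0, 2 * pi)) / h,
      numeric(len)))
    burst_env <- sin(pi * seq_len(len) / len)^2
    x[(at + 1L):(at + len)] <- x[(at + 1L):(at + len)] +
      spec$snore_intensity * stack * burst_env / 3
  }

  # respiratory pauses: Poisson count at the target hourly rate, placed
  # without overlap by stick-breaking (spacings between gaps get a Dirichlet
  # share of the free time, with >= 5 s of breathing between gaps). An
  # expected gap load that cannot fit in the night is an infeasible spec;
  # an unlucky draw that merely exceeds the feasible count is truncated to
  # the maximum that fits, mimicking event saturation in dense apnea.
  mean_dur <- mean(spec$apnea_duration_range_s)
  if (spec$target_ahi / 3600 * spec$duration_s * (mean_dur + 5) >
      0.9 * spec$duration_s)
    stop("synth_breathing_audio: infeasible spec: expected gap time exceeds duration")
  lam <- spec$target_ahi * spec$duration_s / 3600
  n_gaps <- stats::rpois(1L, lam)
  events <- data.frame(start_s = numeric(0), duration_s = numeric(0))
  if (n_gaps > 0L) {
    durs <- stats::runif(n_gaps, spec$apnea_duration_range_s[1L],
                         spec$apnea_duration_range_s[2L])
    while (n_gaps > 0L && sum(durs) + 5 * n_gaps > 0.95 * spec$duration_s) {
      n_gaps <- n_gaps - 1L           # saturation: drop the latest draws
      durs <- durs[seq_len(n_gaps)]
    }
  }
  if (n_gaps > 0L) {
    slack <- spec$duration_s - sum(durs) - 5 * n_gaps
    shares <- stats::rexp(n_gaps + 1L)
    spacing <- c(0, rep(5, n_gaps - 1L)) +
      slack * shares[seq_len(n_gaps)] / sum(shares)
    starts <- cumsum(spacing) + cumsum(c(0, durs))[seq_len(n_gaps)]
    events <- data.frame(start_s = starts, duration_s = durs)
    for (i in seq_len(n_gaps)) {
      a <- max(1L, round(events$start_s[i] * spec$rate))
      b <- min(n, round((events$start_s[i] + events$duration_s[i]) * spec$rate))
      x[a:b] <- 0
    }
  }

  x <- x + spec$noise_floor * stats::rnorm(n)
  x <- pmax(pmin(x, 1), -1)
  list(rec = audio_recording(x, spec$rate, subject_id),
       events = events, snores = length(snore_at))
}

# sleep-stage Markov chain: N2-dominant with occasional N3/REM excursions
.hypnogram_chain <- function() {
  P <- matrix(0, 5, 5, dimnames = list(c("W", "N1", "N2", "N3", "REM"),
                                       c("W", "N1", "N2", "N3", "REM")))
  P["W", ] <- c(0.50, 0.45, 0.05, 0.00, 0.00)
  P["N1", ] <- c(0.05, 0.30, 0.60, 0.00, 0.05)
  P["N2", ] <- c(0.02, 0.05, 0.78, 0.08, 0.07)    # stationary N2+N3 ~ 0.70
  P["N3", ] <- c(0.00, 0.00, 0.20, 0.80, 0.00)
  P["REM", ] <- c(0.02, 0.05, 0.13, 0.00, 0.80)
  P
}

#' Generate a synthetic hypnogram
#'
#' Markov-chain stage sequence with N2-dominant dwell (stage-2/3 non-REM
#' occupies most of the night, as in scored polysomnography). The chain's
#' transition matrix is available via
#' `attr(synth_hypnogram(...), "chain")` for oracle checks.
#'
#' @param duration_s recording duration to cover (s), >= one epoch.
#' @param epoch_s scoring epoch (s), default 30.
#' @param seed integer seed.
#' @return a [hypnogram()] with attribute `chain`.
#' @export
synth_hypnogram <- function(duration_s, epoch_s = 30, seed = 1L) {
  if (duration_s < epoch_s) stop("synth_hypnogram: duration shorter than epoch")
  set.seed(seed)
  P <- .hypnogram_chain()
  n <- ceiling(duration_s / epoch_s)
  st <- character(n)
  st[1L] <- "N2"   # recordings are treated as trimmed to sleep onset
  for (k in seq_len(n - 1L))
    st[k + 1L] <- sample(colnames(P), 1L, prob = P[st[k], ])
  out <- hypnogram(st, epoch_s)
  attr(out, "chain") <- P
  out
}

#' Generate a synthetic severity cohort
#'
#' Draws per-group AHI values from the severity definition ranges (normal
#' U\[0,5), mild U\[5,15), moderate U\[15,30), severe U\[30,80)) and assigns
#' group-stepped snore intensity (0.05/0.15/0.30/0.50). Recordings are not
#' materialized here — each subject's audio can be gigabytes-scale — use
#' [realize_subject()] or [cohort_feature_table()] to generate them one at
#' a time.
#'
#' @param n_per_group subjects per severity group (>= 2).
#' @param duration_s per-subject recording length (s), default 1200 (20
#'   min: long enough for stable window statistics and several planted
#'   gaps at moderate AHI).
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @return a `synth_cohort`: list with `roster` (subject_id, ahi,
#'   severity_group) and `specs` (list of [synth_subject_spec()], plus
#'   per-subject hypnogram seeds).
#' @export
synth_cohort <- function(n_per_group = 30L, duration_s = 1200, seed = 1L) {
  if (n_per_group < 2L) stop("synth_cohort: n_per_group must be >= 2")
  set.seed(seed)
  ranges <- list(normal = c(0, 5), mild = c(5, 15),
                 moderate = c(15, 30), severe = c(30, 80))
  snore_gain <- c(normal = 0.05, mild = 0.15, moderate = 0.30, severe = 0.50)
  rows <- list(); specs <- list()
  i <- 0L
  for (g in names(ranges)) {
    for (j in seq_len(n_per_group)) {
      i <- i + 1L
      ahi <- stats::runif(1, ranges[[g]][1L], ranges[[g]][2L])
      sid <- sprintf("S%03d_%s", i, g)
      sub_seed <- (seed * 1000L + i) %% .Machine$integer.max
      rows[[i]] <- data.frame(subject_id = sid, ahi = ahi)
      specs[[i]] <- list(
        spec = synth_subject_spec(ahi, duration_s,
                                  snore_intensity = snore_gain[[g]],
                                  seed = sub_seed),
        hyp_seed = sub_seed + 500000L,
        subject_id = sid)
    }
  }
  roster <- do.call(rbind, rows)
  roster$severity_group <- severity_from_ahi(roster$ahi)
  structure(list(roster = roster, specs = specs, seed = seed,
                 duration_s = duration_s),
            class = "synth_cohort")
}

#' Materialize one cohort subject
#'
#' @param cohort a `synth_cohort`.
#' @param i subject index (row of `cohort$roster`).
#' @return list with `rec`, `hyp`, `events`, `snores`, `subject_id`.
#' @export
realize_subject <- function(cohort, i) {
  stopifnot(inherits(cohort, "synth_cohort"))
  s <- cohort$specs[[i]]
  audio <- synth_breathing_audio(s$spec, s$subject_id)
  hyp <- synth_hypnogram(s$spec$duration_s, seed = s$hyp_seed)
  c(audio, list(hyp = hyp, subject_id = s$subject_id))
}

#' Feature table for a whole synthetic cohort
#'
#' Realizes each subject in turn (audio is discarded after use), runs the
#' preprocessing and feature-extraction stages, and stacks the per-subject
#' feature vectors. Ground truth (planted gap count and total gap seconds)
#' is returned alongside for recovery tests.
#'
#' @param cohort a `synth_cohort`.
#' @param preprocess run [preprocess_recording()] first (default `TRUE`).
#' @param window_seconds analysis window (s), default 5.
#' @param config overrides forwarded to [extract_subject_features()] and
#'   [preprocess_recording()].
#' @param verbose print one line per subject to stderr.
#' @return list with `features` (subjects x features matrix, rownames =
#'   subject ids), `roster`, `truth` (data.frame with `n_gaps`,
#'   `gap_seconds`).
#' @export
cohort_feature_table <- function(cohort, preprocess = TRUE,
                                 window_seconds = 5, config = list(),
                                 verbose = FALSE) {
  stopifnot(inherits(cohort, "synth_cohort"))
  n <- nrow(cohort$roster)
  feats <- NULL
  truth <- data.frame(subject_id = cohort$roster$subject_id,
                      n_gaps = integer(n), gap_seconds = numeric(n),
                      apnea_occupancy = numeric(n))
  for (i in seq_len(n)) {
    sub <- realize_subject(cohort, i)
    rec <- sub$rec
    if (preprocess) rec <- preprocess_recording(rec, sub$hyp, config)
    if (isTRUE(attr(rec, "empty")))
      stop("cohort_feature_table: stage filter removed all audio for ",
           sub$subject_id)
    v <- extract_subject_features(rec, window_seconds, config)
    lev <- mark_apnea_candidates(quantize_levels(rec))
    truth$apnea_occupancy[i] <- qtm_occupancy(transition_matrix(lev))["APNEA"]
    if (is.null(feats))
      feats <- matrix(NA_real_, n, length(v),
                      dimnames = list(cohort$roster$subject_id, names(v)))
    feats[i, ] <- v
    truth$n_gaps[i] <- nrow(sub$events)
    truth$gap_seconds[i] <- sum(sub$events$duration_s)
    rm(sub, rec)
    invisible(gc(FALSE))   # large transient audio buffers; keep heap flat
    if (verbose) message(sprintf("  [%d/%d] %s: %d gaps", i, n,
                                 cohort$roster$subject_id[i], truth$n_gaps[i]))
  }
  list(features = feats, roster = cohort$roster, truth = truth)
}
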