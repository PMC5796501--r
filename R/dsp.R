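# Internal DSP primitives: windows, framing, STFT, filterbanks, LPC,
# frequency-weighting curves. Everything here is deterministic, pure and
# vectorised across frames; higher-level feature code composes these.

# memo cache for analysis matrices (mel/DCT/CQ/gammatone); keyed by
# constructor name + arguments, so repeated per-window calls are O(1)
.dsp_cache <- new.env(parent = emptyenv())

.cached <- function(..., fn) {
  key <- paste(c(substitute(fn), ...), collapse = "|")
  if (is.null(.dsp_cache[[key]])) .dsp_cache[[key]] <- fn(...)
  .dsp_cache[[key]]
}

.hann <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n)  # periodic: COLA at hop = n/2
}

# Frame a signal into a (frame_len x n_frames) matrix, hop samples apart.
.frame_signal <- function(x, frame_len, hop) {
  n <- length(x)
  n_frames <- if (n < frame_len) 0L else 1L + (n - frame_len) %/% hop
  if (n_frames == 0L) return(matrix(numeric(0), nrow = frame_len, ncol = 0))
  if (hop * 2L == frame_len && n %% hop == 0L) {
    # 50% hop: adjacent half-frame blocks tile the signal, so framing is a
    # pure reshape (rbind of shifted column views) — no index matrix
    H <- matrix(x, nrow = hop)
    nc <- ncol(H)
    return(rbind(H[, seq_len(nc - 1L), drop = FALSE],
                 H[, 2L:nc, drop = FALSE]))
  }
  idx <- rep((seq_len(n_frames) - 1L) * hop, each = frame_len) +
    rep.int(seq_len(frame_len), n_frames)
  matrix(x[idx], nrow = frame_len)
}

# STFT: windowed frames -> complex spectrum matrix (n_bins x n_frames),
# one-sided (bins 0 .. fft/2). fft_len defaults to frame_len.
.stft <- function(x, frame_len, hop, window = .hann(frame_len)) {
  frames <- .frame_signal(x, frame_len, hop) * window
  if (ncol(frames) == 0L)
    return(list(S = matrix(complex(0), frame_len %/% 2L + 1L, 0),
                frame_len = frame_len, hop = hop, n = length(x)))
  S <- stats::mvfft(frames)[seq_len(frame_len %/% 2L + 1L), , drop = FALSE]
  list(S = S, frame_len = frame_len, hop = hop, n = length(x))
}

# Inverse STFT by overlap-add; window must satisfy COLA at the hop used
# (Hann at 50% hop does). Returns a signal of the original length.
.istft <- function(S, frame_len, hop, n, window = .hann(frame_len)) {
  n_bins <- frame_len %/% 2L + 1L
  stopifnot(nrow(S) == n_bins)
  n_frames <- ncol(S)
  # rebuild full spectrum with conjugate symmetry
  full <- matrix(complex(real = 0), frame_len, n_frames)
  full[seq_len(n_bins), ] <- S
  if (frame_len > 2L)
    full[(n_bins + 1L):frame_len, ] <- Conj(S[(n_bins - 1L):2L, , drop = FALSE])
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / frame_len
  frames <- frames * window
  total <- n + frame_len + hop * n_frames
  out <- numeric(total)
  wsum <- numeric(total)
  w2 <- window^2
  if (hop * 2L == frame_len) {
    # 50% overlap: frames with the same parity tile contiguously, so the
    # whole overlap-add collapses to two vector additions
    for (par in 0:1) {
      js <- seq(par + 1L, n_frames, by = 2L)
      if (!length(js)) next
      at <- par * hop
      span <- length(js) * frame_len
      block <- frames[, js, drop = FALSE]
      dim(block) <- NULL
      out[(at + 1L):(at + span)] <- out[(at + 1L):(at + span)] + block
      wsum[(at + 1L):(at + span)] <- wsum[(at + 1L):(at + span)] +
        rep.int(w2, length(js))
    }
  } else {
    for (j in seq_len(n_frames)) {
      at <- (j - 1L) * hop
      out[(at + 1L):(at + frame_len)] <- out[(at + 1L):(at + frame_len)] + frames[, j]
      wsum[(at + 1L):(at + frame_len)] <- wsum[(at + 1L):(at + frame_len)] + w2
    }
  }
  out <- out / pmax(wsum, 1e-12)
  out[seq_len(n)]
}

.fft_freqs <- function(frame_len, rate) (0:(frame_len %/% 2L)) * rate / frame_len

# ---------------------------------------------------------------------------
# Mel filterbank (HTK-style mel scale), triangular filters, for MFCC.

.hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
.mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

.mel_filterbank <- function(n_filters, n_bins, rate, fmin = 0, fmax = rate / 2) {
  frame_len <- (n_bins - 1L) * 2L
  mel_pts <- seq(.hz_to_mel(fmin), .hz_to_mel(fmax), length.out = n_filters + 2L)
  hz_pts <- .mel_to_hz(mel_pts)
  bin_f <- .fft_freqs(frame_len, rate)
  fb <- matrix(0, n_filters, n_bins)
  for (i in seq_len(n_filters)) {
    lo <- hz_pts[i]; ce <- hz_pts[i + 1L]; hi <- hz_pts[i + 2L]
    up <- (bin_f - lo) / (ce - lo)
    dn <- (hi - bin_f) / (hi - ce)
    fb[i, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# Orthogonal DCT-II matrix (n_out x n_in), as used for cepstra.
.dct_matrix <- function(n_out, n_in) {
  k <- 0:(n_out - 1L)
  n <- 0:(n_in - 1L)
  M <- cos(pi / n_in * outer(k, n + 0.5))
  M <- M * sqrt(2 / n_in)
  M[1, ] <- M[1, ] / sqrt(2)
  M
}

# ---------------------------------------------------------------------------
# Log-frequency (constant-Q) analysis: a kernel mapping FFT bins to
# geometrically spaced bins, 12 per octave from fmin up to Nyquist.
# Triangular kernels in log2-frequency give constant-Q resolution without a
# per-bin transform; adequate because downstream use is cepstral/statistical.

.cq_kernel <- function(n_bins_fft, rate, fmin = 32.703, bins_per_octave = 12L) {
  frame_len <- (n_bins_fft - 1L) * 2L
  n_oct <- log2((rate / 2) / fmin)
  n_cq <- floor(n_oct * bins_per_octave)
  cq_f <- fmin * 2^((0:(n_cq - 1L)) / bins_per_octave)
  bin_f <- .fft_freqs(frame_len, rate)
  K <- matrix(0, n_cq, n_bins_fft)
  half_bw <- 1 / bins_per_octave  # half-width in octaves
  lf <- log2(pmax(bin_f, 1e-6))
  for (i in seq_len(n_cq)) {
    w <- pmax(0, 1 - abs(lf - log2(cq_f[i])) / half_bw)
    s <- sum(w)
    # low CQ bins can fall between FFT bins; fall back to nearest bin
    if (s < 1e-9) { w[which.min(abs(bin_f - cq_f[i]))] <- 1; s <- 1 }
    K[i, ] <- w / s
  }
  attr(K, "freqs") <- cq_f
  K
}

# ---------------------------------------------------------------------------
# LPC by Levinson-Durbin, vectorised across frames.
# Input: autocorrelation matrix R ((order+1) x n_frames). Output: coefficient
# matrix A (order x n_frames) with prediction model x[t] ~ sum a_k x[t-k].

.levinson <- function(R, order) {
  n_frames <- ncol(R)
  A <- matrix(0, order, n_frames)
  # tiny ridge on lag 0: keeps the recursion stable for near-singular
  # autocorrelations (pure tones), equivalent to adding -120 dB white noise
  R[1, ] <- R[1, ] * (1 + 1e-6)
  E <- pmax(R[1, ], 1e-12)
  for (m in seq_len(order)) {
    if (m == 1L) {
      acc <- R[2, ]
    } else {
      acc <- R[m + 1L, ] - colSums(A[1:(m - 1L), , drop = FALSE] *
                                     R[m:2, , drop = FALSE])
    }
    k <- acc / E
    k[!is.finite(k)] <- 0
    k <- pmax(pmin(k, 0.999999), -0.999999)
    Anew <- A
    Anew[m, ] <- k
    if (m > 1L) {
      Anew[1:(m - 1L), ] <- A[1:(m - 1L), , drop = FALSE] -
        rep(k, each = m - 1L) * A[(m - 1L):1, , drop = FALSE]
    }
    A <- Anew
    E <- pmax(E * (1 - k^2), 1e-15)
  }
  A
}

# Autocorrelation (lags 0..order) per frame. For the small orders used
# here direct lagged products beat the FFT route.
.frame_autocorr <- function(frames, order) {
  flen <- nrow(frames)
  ac <- matrix(0, order + 1L, ncol(frames))
  ac[1L, ] <- colSums(frames^2)
  for (k in seq_len(order))
    ac[k + 1L, ] <- colSums(frames[seq_len(flen - k), , drop = FALSE] *
                              frames[(k + 1L):flen, , drop = FALSE])
  ac
}

# LPC spectral envelope |1/A(e^jw)| in dB on a frequency grid.
.lpc_envelope_db <- function(a, gain, rate, n_grid = 512L) {
  f <- seq(0, rate / 2, length.out = n_grid)
  w <- 2 * pi * f / rate
  k <- seq_along(a)
  Aw <- 1 - colSums(a * exp(-1i * outer(k, w)))
  env <- sqrt(pmax(gain, 1e-15)) / pmax(Mod(Aw), 1e-12)
  list(freq = f, db = 20 * log10(pmax(env, 1e-12)))
}

# ---------------------------------------------------------------------------
# Gammatone filterbank magnitude response. 4th-order gammatone magnitude is
# well approximated by |H(f)| = (1 + ((f - fc)/b)^2)^(-2) with
# b = 1.019 * ERB(fc); channels on the ERB-rate scale.

.erb <- function(f) 24.7 * (4.37 * f / 1000 + 1)
.hz_to_erbrate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
.erbrate_to_hz <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

# Weight matrix (n_channels x n_bins): squared magnitude response of each
# gammatone channel at the FFT bin frequencies.
.gammatone_weights <- function(n_bins, rate, n_channels = 32L,
                               fmin = 50, fmax = min(rate / 2, 4000) * 0.975) {
  frame_len <- (n_bins - 1L) * 2L
  bin_f <- .fft_freqs(frame_len, rate)
  fc <- .erbrate_to_hz(seq(.hz_to_erbrate(fmin), .hz_to_erbrate(fmax),
                           length.out = n_channels))
  W <- matrix(0, n_channels, n_bins)
  for (i in seq_len(n_channels)) {
    b <- 1.019 * .erb(fc[i])
    W[i, ] <- (1 + ((bin_f - fc[i]) / b)^2)^(-4)  # |H|^2 for 4th order
  }
  attr(W, "fc") <- fc
  W
}

# ---------------------------------------------------------------------------
# IEC 61672 frequency weightings, analytic pole form; returns weights on a
# LINEAR amplitude scale (1.0 at 1 kHz by the standard's normalisation).

.a_weight_lin <- function(f) {
  f2 <- f^2
  ra <- (12194^2 * f2^2) /
    ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  ra * 10^(2.00 / 20)
}

.c_weight_lin <- function(f) {
  f2 <- f^2
  rc <- (12194^2 * f2) / ((f2 + 20.6^2) * (f2 + 12194^2))
  rc * 10^(0.06 / 20)
}
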