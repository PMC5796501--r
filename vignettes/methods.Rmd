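---
title: "Acoustic screening of sleep disordered breathing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic screening of sleep disordered breathing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdbscreen)
```

## The screening problem

Sleep disordered breathing (SDB) — repetitive partial or complete collapse
of the upper airway during sleep — is diagnosed by attended polysomnography
(PSG) and graded by the apnea–hypopnea index (AHI, respiratory events per
hour): normal below 5, mild 5–15, moderate 15–30, severe at or above 30.
PSG is expensive and capacity-limited. The premise of this package is that
a bedside microphone already carries most of the screening signal: airway
narrowing changes the spectrum of breathing and snoring sounds, and apneas
interrupt the breathing rhythm itself. `sdbscreen` turns an overnight
single-channel recording into a per-subject acoustic feature vector, selects
the features that statistically separate severity groups (the *acoustic
biomarker*), and evaluates severity classifiers under cross-validation.

## Preprocessing

Overnight recordings mix breathing with stationary machine hum and
transient noise (conversation, duvet movement). Two filters are applied, in
a fixed order:

1. **Spectral subtraction.** Boll-style magnitude subtraction on a 32-ms
   Hann STFT with 50% hop: output magnitude
   $\max(|X| - \alpha N, \beta |X|)$ with oversubtraction $\alpha = 1$ and
   spectral floor $\beta = 0.02$, phase reuse and overlap-add resynthesis.
   The noise profile $N$ is the mean magnitude of the quietest 10% of
   frames, ranked by frame energy: overnight audio has no guaranteed clean
   lead-in, but breathing is intermittent, so the quietest frames are
   dominated by the stationary background. The signal is padded by one
   frame on each side before analysis; otherwise the frames at the edges
   are divided by a near-zero window-weight sum during resynthesis and
   produce large boundary artifacts. For overnight-scale inputs the
   subtraction is streamed in 60-s chunks with one-frame overlap-save at
   the joins (numerically identical to the one-shot transform, but with a
   flat memory profile).
2. **Sleep-stage filtering.** Given a scored hypnogram (30-s epochs by
   default, the standard PSG scoring unit), only stage-2/3 non-REM epochs
   are retained, where respiration is stable and movement noise minimal.
   Kept epochs are concatenated, not muted: downstream statistics are
   per-window, and removal (not zeroing) matches the reduced effective
   recording length that motivates the filter. Without a hypnogram the
   stage filter is skipped with a warning, supporting screening-only use
   with, e.g., actigraphy-based staging.

The subtraction order matters: running it before concatenation means epoch
joins never create subtraction artifacts.

## The feature bank

Each recording is cut into contiguous, non-overlapping 5-s windows (2.5,
7.5 and 10 s are supported alternatives; a trailing partial window is
dropped rather than zero-padded to avoid diluting energy statistics). An
8-h night yields 5760 windows. Within a window, spectral features are
computed on internal 32-ms Hann frames at 50% hop and averaged, so each
window contributes one value per feature.

The bank covers: spectral centroid/rolloff/flux, compactness (log-spectrum
irregularity), spectral variability, RMS, fraction of low-energy 100-ms
sub-windows (below the window-mean sub-window RMS), zero crossings, beat
statistics from the frame-RMS envelope autocorrelation over the 40–200 BPM
lag range, three "strongest frequency" estimates (via zero crossings,
centroid, and FFT maximum), 13 MFCCs (26 mel filters), 13 constant-Q
cepstral coefficients, 10 LPC coefficients (Levinson–Durbin, order 10,
with a $10^{-6}$ ridge on lag 0 for stability on near-singular
autocorrelations), five spectral moments, the log-RMS-derivative, and four
families of 2-D "area" moments over 10-frame spectrogram/cepstrogram
patches (coordinates normalized to the unit square; entry one is the total
mass, the rest are raw moments up to order 3). Feature definitions follow
the published conventions of the jAudio extractor family; they are
reimplemented from the definitions, and numeric agreement with any
particular tool is out of scope.

The constant-Q analysis is realized as a log-frequency kernel: triangular
weights in $\log_2$ frequency, 12 bins/octave from 32.7 Hz to Nyquist,
applied to the 32-ms FFT magnitudes. A per-bin windowed transform would be
slower and, after the log–DCT cepstral collapse and night-level averaging,
statistically indistinguishable for this use.

Three extra families have screening-specific value:

* **Formant amplitudes** F1–F3: amplitudes (dB) of the first three local
  maxima of an order-10 LPC envelope, in ascending frequency. Envelope
  peaks, not raw FFT peaks, are used for robustness to spectral fine
  structure; flat-spectrum windows with fewer than three peaks are filled
  at the band edge and flagged.
* **Gammatone sub-band energies** sb1–sb8: 4th-order Gammatone magnitude
  responses on ERB-spaced centre frequencies, channel energies summed into
  eight 500-Hz bands over 0–4 kHz.
* **Weighted sound pressure levels**: A-, C- and un-weighted RMS and peak
  levels, via the IEC 61672 analytic responses applied in the frequency
  domain (both curves 0 dB at 1 kHz). Recordings are uncalibrated, so all
  levels are dB re full scale plus a configurable calibration offset; only
  within-cohort contrasts matter for selection.

Degenerate (all-zero) windows produce finite floor-valued features — RMS 0,
ZC 0, MFCCs at the log-floor constant, SPLs clamped at −120 dB — never NaN,
so aggregation is total.

**Aggregation.** Bank features contribute the mean and sample SD (n−1) of
their per-window series and of its first difference (temporal change);
formant/sub-band/SPL variables contribute max, min, mean, SD. Names follow
`<feature>[_d1]_<stat>`; the schema is locked and identical across
subjects, and a regression test confirms that every entry of the published
discriminator table resolves to exactly one schema name.

## The quantized transition matrix

Per-window statistics discard the ordering of the night. The qTM restores
it cheaply: the magnitude envelope (1-s frame RMS) is quantized into
SILENCE / LOW / HIGH via thresholds, maximal silence runs lasting 20–60 s
are relabelled APNEA (breathing cessations of at least 20 s are the
clinical apnea criterion; longer silences are treated as non-respiratory
and stay at the silence level), and the 4×4 row-stochastic matrix of
frame-to-frame level transitions is flattened into 16 features.

Numerical choices: the 1-s frame resolves the 20-s bound at 5%
granularity while smoothing waveform oscillation. Thresholds are
per-subject adaptive because recordings are uncalibrated: the silence cut
is the *larger* of the 15th-percentile frame magnitude and an absolute
noise-floor estimate (twice the 2nd-percentile magnitude), the high cut the
85th percentile. The noise-floor term is essential at both extremes: in
high-AHI nights more than 15% of frames are genuinely silent, so a pure
quantile falls inside the silence cluster and fragments apnea-length runs;
in quiet nights it promotes breathing troughs to silence. Zero-occupancy
rows emit zeros rather than uniform probabilities, keeping absent levels
informative.

## Biomarker selection

For each feature, a classical one-way fixed-effects ANOVA screens for any
group difference; screened features get Tukey–Kramer HSD p-values for all
six group pairs (studentized range on the pooled within-group variance,
Kramer-adjusted for unequal sizes). A feature is a *discriminator for group
G* when all three pairs (G, other) are significant at $\alpha = 0.05$; the
acoustic biomarker is the ordered deduplicated union of the four groups'
sets. Requiring three simultaneous rejections makes per-group false
discovery far rarer than $\alpha$ — verified by simulation. No
multiple-testing correction is applied across features, reproducing the
usual per-feature-alpha convention in this literature; a Benjamini–Hochberg
option exists but is off by default. Degenerate zero-variance features are
flagged; with equal means they report p = 1, with unequal means p = 0 (the
statistically meaningful limit).

An SVM-based ranking (`svm_rank_features`) complements the tests: features
are standardized, a linear one-vs-rest SVM is fitted, and recursive feature
elimination removes the bottom 10% by summed squared weights per round;
elimination order reversed is the ranking, with column-order tie-breaks.

## Classification

Three families, all deterministic given a seed: ridge multinomial logistic
regression (glmnet, $\lambda = 10^{-3}$, standing in for boosted
simple-logistic learners), a linear SVM (squared-hinge L2 primal via BFGS;
a polynomial kernel of exponent 1.0 *is* the linear kernel, C = 1), and a
small dense network (hidden layers 50 and 25, ReLU, dropout 0.2 before the
output layer, softmax output, Adam with 200 epochs, batch 16, plateau
early-stopping — optimizer details are unstated upstream and are documented
configuration here, not received facts). SVM "probabilities" are a softmax
over decision values: a normalization convention, not calibrated
probabilities.

Evaluation is stratified 10-fold cross-validation (disjoint 9:1 splits),
features standardized with training-fold statistics only. Stratification is
a deliberate choice for balanced 30-per-group designs: it stabilizes
small-N CV without changing the expected split. Discriminator selection can
be **fixed upfront** (computed once on all subjects — mirroring the
apparent published procedure, where selection precedes evaluation) or
**refit inside every training fold** (the leakage-free mode). The two
answer different questions; the chance-level acceptance test uses the refit
mode, because upfront selection on the evaluation data is exactly the
leakage the guard exists to catch. Multiclass ROC areas are macro-averaged
one-vs-rest rank statistics; classes with no positives report missing, not
zero.

Binary screening tasks relabel subjects by AHI at thresholds 5, 15 or 30
(label 1 when AHI ≥ threshold).

## The synthetic world

The generator states a simplified overnight world so every stage is
testable without clinical data: band-limited noise amplitude-modulated at a
4-s breathing period; snore bursts (5-harmonic stacks, fundamental drawn
from 80–300 Hz) riding inhale peaks with probability and gain stepped by
severity group (0.05/0.15/0.30/0.50); respiratory pauses as a Poisson
process at the subject's target AHI with durations uniform on 10–60 s — so
sub-20-s gaps exercise the "stays silence" branch and 20–60-s gaps the
apnea-candidate branch; a stationary noise floor (RMS 0.005) underneath;
8 kHz sampling. Gaps are placed without overlap by stick-breaking with a
5-s minimum breathing interval; a spec whose *expected* gap load exceeds
the night errors as infeasible, while an unlucky draw is truncated to what
fits (event saturation, as in dense clinical apnea). Cohorts draw AHI
uniformly inside each severity band (severe capped at 80/h) with 30
subjects per group by default; hypnograms come from an N2-dominant Markov
chain whose stationary stage-2/3 occupancy sits in the scored-PSG range.

What a green end-to-end test establishes — and what it does not: the
synthetic world has stepwise group-dependent snore gains and an AHI-driven
gap process, so high cross-validated accuracy demonstrates that the
pipeline's plumbing, selection and evaluation recover *planted* structure
without leakage. It does not establish clinical performance: no airway
physiology, positional effects, inter-subject acoustic variability or
recording-chain diversity are modelled, and published cohort-specific
accuracies are out of scope by design.

## Known limitations

* Feature definitions are reimplementations of published conventions;
  bit-level agreement with the original Java/Weka tooling is a non-goal.
* The qTM frame length, thresholds and the choice to compute it on the
  preprocessed signal are documented defaults, not received facts.
* SPL values are relative (dB re full scale) unless a calibration offset is
  supplied.
* The MLP is deliberately small and will underperform the linear models on
  small cohorts — consistent with the upstream observation that deep
  models need more subjects than a 120-patient design provides.
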