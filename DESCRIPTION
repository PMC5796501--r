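Package: sdbscreen
Title: Acoustic Biomarker Screening for Sleep Disordered Breathing Severity
Version: 0.1.0
Authors@R:
    person("SDB Acoustics", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to screen sleep disordered breathing (SDB) severity from
    overnight breathing-sound recordings. Implements spectral-subtraction
    denoising and sleep-stage filtering of single-channel audio, windowed
    extraction of a broad bank of temporal and spectral audio features
    (MFCC, constant-Q cepstra, LPC, spectral moments, formant amplitudes,
    Gammatone sub-band energies, A/C-weighted sound pressure levels), a
    quantized transition matrix (qTM) summarising overnight magnitude-level
    dynamics including apnea-candidate silences, selection of severity-group
    discriminator features by one-way ANOVA with Tukey HSD post-hoc tests,
    and classification of subjects into apnea-hypopnea index (AHI) severity
    groups under stratified cross-validation. A seeded synthetic-cohort
    generator provides AHI-controlled overnight recordings so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
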