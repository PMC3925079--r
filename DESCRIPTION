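Package: bssfor
Title: Bayesian Spatio-Spectral Filter Optimization for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-class motor-imagery brain-computer interfacing:
    particle-based posterior estimation over discriminative frequency bands
    (each band hypothesis carrying a common-spatial-pattern filter bank and a
    linear discriminant classifier), fixed-band and heuristic-band CSP
    baselines with chronological cross-validation, an unsupervised
    resting-state spectral pipeline (Welch power spectra, 1/f noise-floor
    fitting, band-likelihood densities, subject weighting), and a
    cluster-distance linear regression that predicts a subject's future BCI
    performance from two minutes of resting EEG. Includes a synthetic-EEG
    cohort generator with known ground truth (planted rhythms, noise-model
    parameters, event-related desynchronization, performance structure), EDF
    and plain-matrix readers, Laplacian montage derivation, and a command-line
    entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
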