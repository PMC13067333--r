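Package: tpeeg
Title: Temporal-Prediction EEG Analysis with a Synthetic Cohort Generator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolchain for the electrophysiology of temporal
    prediction in an occluded-motion timing task: a synthetic cohort
    simulator with known behavioral and oscillatory ground truth (logistic
    observers, 1/f background EEG, event-locked beta suppression, delta-band
    phase resets), psychometric function fitting (point of subjective
    equality and steepness), Morlet wavelet time-frequency power and
    inter-trial phase consistency, cluster-based permutation statistics at
    sensor and source level, and a DICS beamformer on an analytic spherical
    head model. Includes BrainVision and EDF writers/readers and a cohort
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
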