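Package: nightbreath
Title: Sleep/Wake Estimation from Whole-Night Breathing-Sound Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates whole-night sleep/wake state at 30-second epoch
    resolution from a non-contact audio recording of breathing sounds.
    Implements Wiener-type spectral-subtraction noise suppression, acoustic
    event detection with snore-likelihood scoring, breathing-periodicity
    features from the emphasized autocorrelation of interval spectrograms,
    a from-scratch AdaBoost time-series classifier producing a sleep-wake
    likelihood curve, per-subject Otsu thresholding with a time-varying
    early-night offset, sleep-quality parameterization (TST, SL, SE, WASO,
    AwI), an epoch-by-epoch evaluation suite (Cohen's kappa, ROC/AUC,
    Bland-Altman), and a seeded synthetic-night simulator that makes every
    stage testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
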