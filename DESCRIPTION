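Package: ecg2bp
Title: Cuffless Blood Pressure Estimation from Single-Channel ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for continuous, cuffless estimation of
    systolic and diastolic blood pressure from a single ECG channel.
    Includes waveform record I/O (delimited text and a minimal WFDB
    subset), a coupled synthetic ECG/ABP generator with known ground
    truth, signal conditioning (zero-phase low-pass filtering and
    wavelet baseline-wander removal), fixed-length non-overlapping
    segmentation, ABP-derived SBP/DBP label extraction, QRS detection
    with RR-interval and heart-rate analysis, a small one-dimensional
    convolutional neural network regressor trained with Adam on
    mean-squared error, and device-validation style evaluation
    (correlation, error statistics, AAMI mean-error/SD check, BHS
    cumulative-percentage grading, Bland-Altman agreement).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
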