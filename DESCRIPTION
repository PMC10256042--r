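Package: hrvtriad
Title: Heart Rate Variability Analysis over a Rest-Task-Recovery Paradigm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for frequency-domain heart rate variability (HRV) analysis
    of short recordings acquired under a three-behavioral-state paradigm
    (initial rest, a 100-s random-number-generation task, post-task rest).
    Provides R-R interval cleaning (range filter with neighbor-average
    replacement) and uniform resampling at the mean heart rate; maximum-entropy
    (Burg autoregressive) power spectra on sliding 30-s windows updated every
    2 s with LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) band powers; per-condition
    averaging and the nine-feature vector (HF, LF, LF/HF at Rest plus
    Task/Rest and After/Rest ratios); randomness indices of the digit task
    (counting bias, interval bias, digram-concentration RNG index); Fisher
    linear discriminant D-scores with confusion counts, sensitivity,
    specificity and Mahalanobis separation; summary-level test statistics
    (Pearson chi-square, pooled t and one-way ANOVA F reconstructed from
    group n/mean/sd); and synthetic generators for RR traces, feature cohorts
    and digit sequences so the whole pipeline is testable without recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
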