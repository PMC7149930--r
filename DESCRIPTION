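Package: hrnv
Title: Heart Rate n-Variability Analysis and Chest-Pain Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for heart rate n-variability (HRnV), a multi-scale
    representation of beat-to-beat variation in which n adjacent normal
    R-R intervals are summed into composite RRnI (non-overlapping) and
    RRnIm (overlapping, stride m) sequences. Computes the full panel of
    time-domain, frequency-domain (Lomb-Scargle band powers) and
    nonlinear (Poincare, approximate and sample entropy, detrended
    fluctuation analysis) parameters on every derived sequence, detects
    beats in raw single-lead ECG, simulates R-R series, ECG traces and
    patient cohorts with known ground truth, and fits the associated
    risk-stratification pipeline (univariable screening, backward
    stepwise logistic regression, leave-one-out cross-validated ROC
    analysis) for 30-day major adverse cardiac events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    signal
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
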