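Package: lscishock
Title: Laser Speckle Contrast Imaging Toolkit for Peripheral Perfusion and Shock Assessment
Version: 0.1.0
Authors@R: person("LSCI", "Toolkit Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates raw laser speckle image stacks with known flow ground
    truth, computes spatial and temporal speckle contrast and the derived
    perfusion index, inverts contrast-decorrelation models to decorrelation
    time and particle velocity, extracts dual-region-of-interest perfusion
    time series and the ROI difference / normalized ROI difference shock
    statistics, evaluates diagnostic cutoffs (confusion matrices, ROC/AUC
    with the Youden-optimal associated criterion, Mann-Whitney U, Spearman
    rank correlation, Cohen's d, shock index), and computes standard
    heart-rate-variability metrics from RR-interval series. Includes
    synthetic two-group cohort and RR-interval generators so the full
    pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
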