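Package: mrcpbmi
Title: Asynchronous Detection of Motor Intent from Movement-Related
    Cortical Potentials
Version: 0.1.0
Authors@R:
    person("BMI", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating an asynchronous
    electroencephalography (EEG) based brain-machine interface that detects
    motor intent from movement-related cortical potentials (MRCPs). Provides
    a synthetic EEG/EMG/kinematics session generator, causal delta-band
    preprocessing with Large-Laplacian re-referencing, adaptive-window
    feature extraction (slope, negative peak, area, Mahalanobis distance),
    calibration of an RBF-kernel support vector classifier with
    pseudo-online sliding-window cross-validation, window-length
    optimization by ROC area, label-permutation significance testing, and a
    closed-loop replay simulator with EMG-gated decision logic plus
    block-level performance metrics (TPR, FPR, intents per minute,
    detection latency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
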