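Package: motorchart
Title: Motor Growth Charts and Developmental Age Prediction from Wearable
    Label Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for charting infant gross motor development from
    wearable-derived posture and movement label streams. Provides playtime
    detection and quality filtering of frame-level classifier outputs,
    recording-level posture and posture-conditioned movement distribution
    features, developmental age prediction (DAP) by Gaussian process
    regression with leave-one-subject-out evaluation, four-parameter
    logistic growth-chart fitting with bootstrap confidence intervals and
    mixed-model serial-measurement correction, intra-session measurement
    noise estimation, longitudinal DAP tracking, and cross-cohort
    replicability metrics. Includes a parametric synthetic cohort
    generator for motor label streams and physical growth measurements
    with known ground truth, used for validation and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    lme4,
    minpack.lm,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
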