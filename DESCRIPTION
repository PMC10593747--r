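Package: hdtft
Title: Real-Time Prediction of Intradialytic Hypotension and Hypertension
    with an Interpretable Temporal Fusion Network
Version: 0.1.0
Authors@R:
    person("Dialysis", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating real-time predictors of
    intradialytic hypotension (IDH-1: nadir systolic blood pressure below
    90 mmHg; IDH-2: a fall of at least 20 mmHg in systolic pressure or
    10 mmHg in mean arterial pressure from the session-initial reading)
    and intradialytic hypertension (IDHTN: a rise of at least 10 mmHg in
    systolic pressure) over a one-hour horizon during hemodialysis.
    Includes a synthetic-cohort generator with known outcome drivers,
    cohort exclusion filters and previous-session matching, per-timestamp
    outcome labeling, a missingness-aware feature pipeline with auxiliary
    imputation indicators, a modified temporal-fusion-transformer
    classifier (gated residual networks, variable selection, gated
    recurrent encoding, causally masked single-headed attention, and
    previous-session context re-entry) trained with a built-in
    reverse-mode automatic-differentiation engine, attention-based
    variable importance, slim-model schema selection, and evaluation
    utilities (AUROC with DeLong confidence intervals and tests, AUPRC
    with bootstrap intervals, calibration, elapsed-time stratification,
    and simplified recurrent and logistic baselines).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
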