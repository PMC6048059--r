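Package: crowdihc
Title: Crowdsourced Immunohistochemistry Scoring, Calibration and
    Survival Association
Version: 0.1.0
Authors@R:
    person("Alex", "Carey", email = "alex.carey@example.org",
           role = c("aut", "cre"))
Description: Tools for aggregating noisy categorical citizen-scientist
    classifications of tissue-microarray (TMA) core segments into
    per-core and per-patient immunohistochemistry H-scores. Includes
    the three categorical proportion-bin schemes used for crowd
    questioning, 6x6 core tiling with central-segment selection and
    colour inversion, leakage-free linear bias correction calibrated
    against expert gold-standard scores via 10-fold cross-validation
    with clipping, crowd-vs-expert agreement statistics (Spearman rank
    correlation and quadratic-weighted kappa with percentile bootstrap
    confidence intervals), accuracy-versus-number-of-raters curves, and
    Kaplan-Meier / Cox proportional-hazards association of patient
    H-scores with disease-specific survival. A synthetic-crowd
    generator with known ground truth makes every stage testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    survival,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
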