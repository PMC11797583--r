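Package: cubdrisc
Title: Diabetes Risk Scores and Dysglycemia Screening Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores adults on the FINDRISC questionnaire and its Latin-American
    (LA-FINDRISC) and Cuban (CUBDRISC) waist-circumference variants, classifies
    oral glucose tolerance test (OGTT) results into the five glycemic states
    (normal, altered fasting glucose, altered glucose tolerance, both, type 2
    diabetes) and the binary dysglycemia outcome, and evaluates the scales as
    screening tests: confusion tables across integer cutoffs, sensitivity,
    specificity and predictive values with Wilson confidence intervals,
    likelihood ratios with log-method intervals, ROC curves with trapezoidal
    AUC and Hanley-McNeil intervals, optimal-cutoff selection (Youden or
    likelihood-ratio constrained), and Cohen's kappa concordance between
    dichotomized scales with Landis-Koch interpretation. Includes a seeded
    synthetic screening-cohort generator with configurable marginal structure
    and a score-coupled outcome link, plus an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse
Config/testthat/edition: 3
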