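Package: hvsi
Title: Acoustic Scoring of Arteriovenous Fistula Function and Diagnostic
    Evaluation for Hemodialysis Vascular Access Surveillance
Version: 0.1.0
Authors@R:
    person("Tojinkai", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the Hemodialysis Vascular Sound Index (HVSI), a 0-999
    acoustic score of arteriovenous fistula function derived from anastomosis
    sound recordings by short-time Fourier analysis, band filtering,
    rectification and logarithmic normalization. Includes Doppler ultrasound
    hemodynamic formulas (brachial artery flow volume and resistance index), a
    seeded generative model of auscultation sounds and synthetic patient
    cohorts, a diagnostic-accuracy engine (ROC curves, area under the curve
    with DeLong confidence intervals, Youden-index cutoffs, confusion
    statistics, concordance, correlation and regression), propensity-score
    1:1 matching with adjusted logistic odds ratios, a packaged 20-patient
    verification cohort, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
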