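Package: atscore
Title: Adjusted Tokuhashi Scoring and Six-Month Survival Evaluation for
    Spinal Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for six-month survival prediction in surgically treated
    spinal-metastasis patients. Implements the revised Tokuhashi score
    (RTS) rubric, population-standardized BMI Z-scores, and the adjusted
    Tokuhashi score ATS = RTS + a*(target therapy) + b*(Z-BMI), together
    with the machinery used to develop and validate such a score:
    ROC/AUC with DeLong paired comparison, Youden cutoff selection,
    Kaplan-Meier and log-rank survival analysis, logistic prognostic-factor
    models, an exhaustive (a, b) weight search against an AUC objective,
    and a calibrated synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
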