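Package: mapsig
Title: Derivation and Validation of Proliferation-Type Prognostic Gene
    Signatures from Two-Condition Arrays and Survival-Annotated Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for deriving short prognostic gene signatures
    the way proliferation signatures such as the seven-gene MAPS were built:
    two-condition cell-line arrays are filtered with a ROC-estimated intensity
    cutoff and screened with SAM-style permutation statistics at a 2-fold
    cutoff; the resulting gene set is taken into a survival-annotated patient
    cohort where, blind to outcome, uniform genes are eliminated, patients are
    split by k-means (k = 2), genes are filtered by F-test-guided t-tests and
    ranked by single-gene ROC AUC, and the surviving genes form the signature.
    Patients are scored by mean normalized log2 expression and classified by
    the sign of the score. Kaplan-Meier estimation, log-rank testing and Cox
    proportional-hazards regression (Efron ties) are implemented in the
    package and used to evaluate the classes. A seeded synthetic-data module
    generates both input kinds with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
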