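Package: stainclass
Title: Immunohistochemistry Scoring and Diagnostic Evaluation for EGFR
    Mutation-Specific Antibodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for quantifying immunohistochemical (IHC) staining of
    EGFR mutation-specific antibodies (L858R, delE746-A750) in lung
    adenocarcinoma and converting the readings into mutation calls that are
    evaluated against DNA-sequencing ground truth.  Implements quickscore
    (percent x intensity) quantification, logistic-regression combination of
    a mutation-specific score with total-EGFR expression, empirical ROC
    construction with closest-to-corner optimal cutoffs, the DeLong test for
    paired AUC comparison, 2x2 diagnostic-accuracy metrics with the
    rounding conventions used in clinical reporting, and tyrosine-kinase-
    inhibitor outcome analysis (response rates, Kaplan-Meier progression-free
    survival, Cox regression).  A seeded synthetic-cohort generator with a
    configurable total-EGFR-driven cross-reactivity mechanism makes every
    pipeline stage testable without patient data.
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
    optparse,
    withr
Config/testthat/edition: 3
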