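Package: fastscore
Title: Fluid Assessment Scoring Tool (FAST) for Pediatric Fluid Overload
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Fluid Assessment Scoring Tool (FAST), a ten-variable
    composite bedside score (0-3 points per variable) for fluid overload in
    critically ill children, together with its validation machinery:
    non-parametric ROC cut-point tables against a binary thoracic-fluid-content
    reference with exact binomial confidence intervals, empirical and
    cross-validated AUC, Mann-Whitney rank-sum outcome comparisons, exact
    reconstruction of the published 118-encounter score-by-label table from its
    survivor proportions, and a seeded synthetic-cohort simulator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
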