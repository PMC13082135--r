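Package: initsurv
Title: Time-Varying Survival and Causal Models of Adolescent Substance-Use Initiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal time-to-initiation analysis of adolescent
    substance use. Derives per-substance time-to-first-use outcomes from
    harmonized visit-level endorsement data (with religious-context masking and
    follow-up censoring rules), converts visit records into counting-process
    start-stop intervals with leakage-free forward-fill and value-plus-
    availability encoding, screens and fits time-varying Cox proportional
    hazards models with cluster-robust variance and LASSO-based selection, and
    estimates causal effects of time-varying exposures via marginal structural
    models with stabilized inverse-probability-of-treatment weights and pooled
    logistic regression. Includes a synthetic longitudinal cohort generator
    with known causal ground truth (treatment-confounder feedback, calibrated
    event rates) so every stage is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    glmnet,
    sandwich,
    splines,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
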