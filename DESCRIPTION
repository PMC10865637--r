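Package: ctgobs
Title: Observer Performance and Agreement Analysis for Cardiotocography
    Interpretation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for multi-reader observer-performance studies of
    cardiotocography (CTG) interpretation during labor.  Implements
    batched balanced case assignment, diagnostic accuracy metrics
    (success rate, sensitivity, specificity) with Wilson score
    confidence intervals, stratified summaries and per-participant
    TPR/FPR operating points, sample-size calculation for
    sensitivity/specificity studies, a profession-consensus
    interobserver agreement and reliability procedure (proportion of
    agreement and Cohen's kappa with overlap-weighted pooling and a
    case-level bootstrap), and a synthetic annotator-cohort generator
    with a latent logistic rater response model for end-to-end testing
    and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
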