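Package: netstate
Title: Decoding Task-Evoked Brain Network States from Block-Design fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how cognitive tasks are
    encoded in dynamic brain network states. Simulates block-design fMRI
    cohorts with planted task-specific activation and connectivity states
    organised by a psychometric factor structure; estimates block-wise GLM
    activation maps with FDR and minimal-cluster correction and their
    conjunction/union overlap algebra; parcellates statistical volumes with
    a watershed transform; computes psychometric (RBF), Dice and
    activation-pattern task similarities; extracts FIR-residual dynamic
    functional connectivity features; runs error-correcting-output-code
    multi-class classification with repeated subject-level held-out
    evaluation, permutation nulls, stacking, pairwise binary analysis,
    meta-class tests and sparse connection selection; and relates
    per-subject classifiability to a behavioural performance index via
    boosted regression trees on resting-state-network-reduced connectomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
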