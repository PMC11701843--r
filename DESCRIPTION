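Package: mutbench
Title: Cross-Context Generalization Benchmarks for Mutation-Status
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Benchmarks how well transcriptomic mutation-status classifiers
    generalize across datasets and across cancer types. Builds binary
    mutated/non-mutated labels from point mutations plus directional
    copy-number events, filters hypermutated samples, applies cancer-type
    validity and gene-retention rules, sweeps L1-regularized logistic
    regression paths and small fully connected neural networks over
    regularization axes, compares "best" versus "smallest good"
    (one-standard-error) model selection, and evaluates generalization with
    baseline-corrected area under the precision-recall curve, bootstrap
    confidence intervals, and rank analyses. Includes a synthetic multi-context
    cohort generator with controllable covariate shift so the full pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
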