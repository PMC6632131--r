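Package: ecindex
Title: Serum miRNA Diagnostic Index Construction and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and evaluates serum microRNA diagnostic classifiers for
    case-control microarray cohorts. Implements positive-call background
    subtraction, internal-control ratio normalization, robust-miRNA
    filtering, Fisher linear discriminant analysis with greedy beam-search
    feature selection scored by leave-one-out cross-validation, the
    published six-miRNA esophageal squamous cell carcinoma index (EC index)
    as a frozen scorer, diagnostic test evaluation (ROC/AUC with DeLong
    confidence intervals, sensitivity/specificity with Wilson intervals,
    stage and control-cohort subgroups), screening predictive-value
    arithmetic, and a synthetic cohort generator for end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
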