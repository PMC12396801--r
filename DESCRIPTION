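Package: bleedr
Title: Detection of Bleeding Adverse Drug Events in Discharge Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and grades bleeding adverse drug events in hospital
    discharge summaries. Implements a three-stage cascaded sentence
    classifier (bag-of-words logistic regression and linear support vector
    machines with class weighting) with document-level multilabel
    aggregation, a rule-based comparator built on ICD-10-GM code groups
    following ISTH severity criteria, a dual-granularity evaluation
    framework (per-class confusion metrics, micro/macro averaging, ROC/AUC,
    Cohen and Fleiss kappa), and a deterministic synthetic-corpus generator
    that emulates the statistical structure of annotated French clinical
    text so the full pipeline is testable without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    glmnet,
    e1071,
    stringi,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
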