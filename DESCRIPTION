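Package: scMarkerRules
Title: Marker Genes and Quantitative Classification Rules from Labeled
    Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies qualitative cell-type biomarkers and quantitative
    classification rules from labeled single-cell expression matrices
    (log2(TPM+1) scale). The pipeline chains all-relevant feature selection
    by the shadow-attribute (Boruta) scheme, minimum-redundancy
    maximum-relevance (mRMR) mutual-information ranking, and incremental
    feature selection with SMOTE-balanced stratified 10-fold cross-validation
    of CART and random-forest classifiers scored by the multi-class Matthews
    correlation coefficient. From the optimal decision tree it extracts
    root-to-leaf decision rules and per-class exclusive genes, and offers a
    hypergeometric over-representation test against user-supplied gene sets.
    A seeded synthetic-data generator with planted marker genes supports
    offline ground-truth validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    fgsea,
    graphics,
    jsonlite,
    ranger,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
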