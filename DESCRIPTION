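Package: cellstack
Title: Dynamic Stacked-Ensemble Cell-Type Annotation for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Supervised multi-class cell-type identification from single-cell
    RNA-seq expression matrices using a two-layer dynamic stacking ensemble.
    Per cell type, genes are ranked by a one-vs-rest chi-squared statistic and
    the top-k form a type-specific signature; on each signature sub-matrix,
    probabilistic base learners (RBF-SVM and multinomial logistic regression
    by default, optionally random forest, gradient boosting, or a multilayer
    perceptron) produce out-of-fold class-probability features that are
    concatenated into a meta-feature matrix and classified by a multinomial
    logistic-regression meta-learner. Includes per-cell total-count
    normalization, Matrix Market / delimited / h5ad-compatible readers,
    stratified cross-validation and cross-dataset evaluation protocols with
    accuracy, macro-F1 and median-F1 metrics, repeated class-balanced
    down-sampling, and a negative-binomial simulator with planted marker
    genes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    e1071,
    glmnet,
    ranger,
    xgboost,
    nnet,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
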