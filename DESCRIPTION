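Package: hydml
Title: Hybrid Ensemble Feature Selection for Robust Differentially
    Methylated Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies robust differentially methylated loci (DML) from
    array-style DNA methylation beta-value matrices (tumour versus normal)
    with a hybrid ensemble feature-selection procedure: three heterogeneous
    per-locus rankers (elastic-net regression, information gain, Monte Carlo
    random-subspace decision trees) are run inside stratified
    cross-validation folds, aggregated with accuracy weights, filtered by a
    weight threshold, unioned across folds, and consolidated across repeated
    iterations by bagging. Includes a selection-stability measure based on
    the Jaccard index, classification performance metrics, pan-cancer
    consensus utilities (pan-cancer DML selection, hyper/hypo direction
    calls, promoter/gene-body/intergenic annotation, per-chromosome density,
    cross-cancer similarity clustering), and a synthetic-cohort generator
    with planted differential loci for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    e1071,
    ape,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
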