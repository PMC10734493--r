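Package: microcross
Title: Cross-Study Machine Learning for Multi-Cohort Gut Microbiome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Seeded nested cross-validation, a four-algorithm model zoo
    (random forest, extremely randomized trees, gradient-boosted trees and a
    multilayer perceptron), permutation feature importance, cross-study
    ensemble prediction, control augmenting and pipeline search for binary
    classification of multi-cohort gut microbiome feature tables, together
    with a compositional multi-cohort data simulator and the alpha/beta
    diversity stack (rarefaction, Shannon, Bray-Curtis, PCoA,
    Kruskal-Wallis with Benjamini-Hochberg adjustment) used to characterize
    cohorts. Designed for delivery-mode (Caesarean vs vaginal) prediction
    from infant stool 16S genus tables, but agnostic to the binary label.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    vegan,
    withr,
    xgboost,
    yaml
Suggests:
    biomformat,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
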