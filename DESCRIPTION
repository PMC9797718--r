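Package: SynergyNet
Title: Multi-Drug Synergy Prediction and Dose-Response Synergy Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts and ranks the potency of high-order anti-cancer drug
    combinations in individual cell lines, and quantifies experimental
    synergy from dose-response plates. Modeling samples pair a cell line's
    pathway-panel gene expression profile with a binary drug-target
    fingerprint (set union across combination members) and are labeled with
    log-scale IC50 values. A seeded feed-forward neural network (regression
    or classification head) plus KNN, random forest, SVM and gradient
    boosting baselines are trained on monotherapy responses and used to
    rank arbitrary drug subsets by predicted pseudo-IC50. The synergy lab
    fits median-effect dose-response curves, derives IC50s, and computes
    Chou-Talalay combination indices with synergy categories. Includes
    hypergeometric over-representation analysis of combination targets and
    a fully seeded synthetic-world generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    class,
    FNN,
    randomForest,
    e1071,
    xgboost,
    fgsea,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Pharmacogenomics, Regression, Classification,
    GeneExpression
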