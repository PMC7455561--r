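Package: paleosdm
Title: Ensemble Species Distribution Modelling and Niche Overlap for
    Presence-Only Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing species distributions from
    presence-only occurrence records and gridded environmental
    predictors. Implements spatial thinning of occurrence records,
    terrain predictor derivation (Horn slope, topographic
    heterogeneity), stepwise variance-inflation-factor predictor
    selection, five presence/background suitability algorithms (GLM,
    GAM, boosted trees, maximum entropy, random forest) behind a single
    fit/predict contract, ensemble combination, presence-only
    evaluation metrics (AUC, sensitivity, specificity, TSS, continuous
    Boyce index), permutation variable importance, suitable-area
    estimation, and Schoener's D / Hellinger-based niche overlap
    between suitability surfaces. A virtual-species generator produces
    correlated synthetic predictor stacks and occurrence samples with
    known response curves so every stage of the pipeline can be
    validated end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    glmnet,
    randomForest,
    xgboost,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
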