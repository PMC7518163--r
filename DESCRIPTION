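Package: EnsembleSDM
Title: Ensemble Species Distribution Modelling from Presence-Only Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Presence-only ensemble species distribution modelling for
    gridded marine environments. Provides aligned multi-layer environmental
    raster stacks with nearest-neighbour resampling, clipping, seasonal
    averaging and variance-inflation-factor collinearity screening;
    occurrence ingest with seasonal splitting and grid-cell spatial
    thinning; algorithm-family-specific pseudo-absence sampling designs;
    seven base learner families (artificial neural network, classification
    tree, boosted trees, logistic regression, multivariate adaptive
    regression splines, random forest, support vector machine) evaluated by
    repeated 70/30 holdout AUC; AUC-thresholded ensemble habitat-suitability
    maps with between-algorithm variance uncertainty maps; permutation
    variable importance and partial-effect response curves; and a
    virtual-species simulator with known parametric niches for end-to-end
    validation of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    nnet,
    rpart,
    ranger,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    car,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
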