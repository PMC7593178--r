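Package: habtune
Title: Tuning and Evaluation of Species Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified framework for training, tuning and evaluating
    presence/background and presence/absence species distribution models.
    Provides a samples-with-data (SWD) container with hold-out and random
    k-fold partitioning, four trainable model families (artificial neural
    network, boosted regression trees, random forest, and a native
    Maxent-style penalized model with linear/quadratic/product/hinge
    feature expansion), AUC/TSS/AICc evaluation, permutation importance
    with leave-one-out jackknife, data-driven variable selection
    (collinearity removal and parsimony reduction), and three
    hyperparameter tuners: exhaustive grid search, random search, and a
    genetic algorithm. Includes a virtual-species simulator with known
    truth, raster prediction with thresholded maps, response curves, and
    a model report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    nnet,
    randomForest,
    xgboost,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
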