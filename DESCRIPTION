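Package: nichecast
Title: Ensemble Ecological Niche Modelling with Small-Sample Jackknife
    Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An ensemble species distribution modelling pipeline for
    data-poor species: correlation-matrix PCA reduction of climate and
    edaphic raster blocks with broken-stick axis selection and projection
    of current-fitted axes onto future scenarios, disk-constrained
    pseudo-absence sampling, a registry-based multi-algorithm ensemble,
    leave-one-out jackknife validation with MaxSensSpec thresholding and
    an exact Poisson-binomial significance test, majority consensus
    mapping, and present-versus-future suitable-area change accounting.
    Includes a virtual-species simulator so every stage is testable by
    parameter recovery without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    glmnet,
    jsonlite,
    MASS,
    mgcv,
    nnet,
    randomForest,
    rpart,
    splines,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
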