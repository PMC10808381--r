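Package: seedsalt
Title: Salt-Stress Phenotyping of Seed Plates from Fluorescent and
    Visible-Light Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based phenotyping of oilseed (Camelina sativa) seed
    plates. Segments seeds from RGB plate images by combined contour
    tracing and region labeling, extracts 7 morphological and 16
    colorimetric features per seed, converts pixel measurements to
    millimetres via a dish-diameter calibration, classifies each plate's
    salt status by the consensus of 13 binary classifiers, and evaluates
    predictions with accuracy, sensitivity, specificity, precision, F1,
    Fisher's exact test and plate-level k-fold cross-validation. Includes
    a synthetic plate generator with ground-truth masks so the full
    pipeline can be exercised without any imaging hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    jpeg,
    kernlab,
    methods,
    nnet,
    png,
    purrr,
    randomForest,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tiff,
    tree,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
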