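Package: enosegrade
Title: Electronic-Nose Apple Quality Grading with a Hybrid KNN-SVM Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for grading apple quality from a
    six-sensor metal-oxide electronic nose. Generates seedable synthetic sensor
    recordings with grade-dependent plateaus, smooths them with a
    first-principles Savitzky-Golay filter, extracts the 18-dimensional
    max/average/stable feature vectors, reduces dimensionality with PCA or
    Fisher linear discriminant analysis, and classifies grades with a hybrid
    K-nearest-neighbor support vector machine in which a local Gaussian-kernel
    soft-margin SVM is trained on each query's neighborhood. Includes a
    stratified, apple-grouped evaluation harness and baseline classifier
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    class,
    e1071,
    randomForest,
    rpart,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
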