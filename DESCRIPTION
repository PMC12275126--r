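Package: extractopt
Title: Dual-Model Optimization of Ultrasonic Polysaccharide Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for optimizing ultrasonic-assisted extraction processes
    with a four-factor Box-Behnken design and neural-network surrogates.
    Fits the full quadratic response-surface model by ordinary least squares
    with a complete ANOVA (per-term sums of squares, lack-of-fit against
    pure error, PRESS and predicted R-squared), trains a 4-h-1
    backpropagation network with min-max normalization and golden-section
    search over hidden-layer size, and provides a hybrid genetic-algorithm /
    ant-colony (GA-ACO) metaheuristic that evolves candidate weight vectors
    under pheromone guidance to initialize the network. Surrogates are
    compared by R-squared, MAE and RMSE on a stratified train/validation
    split and maximized over the experimental region by grid search with
    coordinate-ascent polishing. Includes a synthetic-data generator for
    quadratic response surfaces with replicated center points, and ships the
    29-run ultrasonic extraction dataset for Tetrastigma hemsleyanum
    polysaccharide yield used throughout the documentation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
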