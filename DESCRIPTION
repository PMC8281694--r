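Package: phenoyield
Title: Plant-Level Yield Prediction from Multi-Date UAV Raster Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for plant-level crop yield analysis from multi-date UAV
    imagery: derivation of plant-height and vegetation-index maps (NDVI, GNDVI,
    WDVI) from surface models and multispectral reflectance rasters, per-plant
    circular-ROI extraction, first-order and gray-level co-occurrence matrix
    (GLCM) texture statistics plus growth rates, five variable-selection
    algorithms (Boruta shadow features, permutation importance, genetic
    algorithm, LASSO, recursive feature elimination), and yield regression with
    random forest, ridge, and support-vector models evaluated by R-squared and
    relative RMSE. A seeded synthetic-field generator with known causal
    structure makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    ranger,
    randomForest,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
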