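Package: fiberknn
Title: Predicting Dietary Fiber in Packaged Foods with Weighted k-Nearest
    Neighbors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts the dietary fiber content of packaged foods and
    beverages from the six nutrients commonly printed on nutrition
    information panels (total sugar, starch, protein, saturated fat,
    unsaturated fat, sodium) using a category-partitioned, inverse-distance
    weighted k-nearest neighbors regression under Manhattan distance.
    Includes record- and category-level exclusion filters for label data,
    min-max feature normalization fitted on training data, brand-grouped
    train/test splitting to prevent leakage of near-identical product
    variants, five-fold cross-validated hyperparameter selection,
    regression and fiber-density classification metrics stratified by
    nearest-neighbor distance, supply-level median/IQR reporting with a
    rank-sum comparison of fiber-reporting and non-reporting products, a
    synthetic packaged-food-supply generator with known ground truth, and a
    command-line interface wiring the steps into a pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
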