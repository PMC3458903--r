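Package: angiomorph
Title: Automated Vessel Inclination Morphometry for Fundus Angiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic analysis of retinal vessel inclination in fundus
    angiograms. An oriented Gaussian matched-filter bank assigns every vessel
    pixel a tangent angle, which is re-expressed relative to the ray from the
    optic-disc centre and summarised over the 2r-3r measurement annulus as
    morphometric features (vessel count, mean and spread of per-vessel angles,
    histogram mode, vessel area fraction). A CART decision tree with Gini
    impurity, cost-complexity pruning at the one-standard-error level and
    stratified cross-validation classifies subjects as healthy or hypertensive
    from those features. Includes a synthetic-phantom generator with analytic
    ground truth, broom-style tidiers, ggplot2 plotting methods and a
    command-line interface for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
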