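Package: noduleant
Title: Ant Colony Optimization Edge Detection and Clustering of Lung
    Nodules in CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection of lung-nodule candidates in 2-D grayscale CT-like
    rasters using ant colony optimization (ACO) edge detection and three
    variants of it (refined, logical, and variant ACO), compared against
    Otsu thresholding, watershed, and seeded region growing.  Edge maps are
    reduced to nodule candidates by connected-component (black circular
    neighborhood) analysis with line rejection, filtered by local mean
    intensity, and grouped into benign/malignant clusters by genetic
    algorithm refined k-means or single-linkage hierarchical clustering.
    Includes a seeded synthetic phantom generator with exact ground truth
    and object/pixel-level detection metrics (recall ratio, sensitivity,
    specificity, accuracy, precision).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
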