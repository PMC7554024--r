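Package: mitoseg
Title: Deep-Learning Segmentation and Morphometry of Mitochondrial
    Fluorescence Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolbox for segmenting mitochondria in 2D fluorescence
    microscopy images and quantifying their morphology. Provides a seeded
    generator of synthetic mitochondrial phenotypes (elongated, fragmented,
    tubular, mixed) with exact ground-truth masks; a training-data pipeline
    with overlapping tiling, U-Net border weight maps, geometric
    augmentation and leave-one-out cross-validation folds; a modified U-Net
    (batch normalization in place of dropout in the contracting pathway)
    with weighted cross-entropy training, tiled prediction and fine-tuning;
    classical Gaussian, Hessian and Laplacian comparator segmenters; a
    morphological accuracy framework (dice coefficient, object-matched fold
    deviation of shape descriptors, normalized energy distances); per-object
    morphometry including skeleton branch statistics; and a nonparametric
    statistics suite (D'Agostino K-squared, Mann-Whitney U, Kruskal-Wallis
    with Dunn's post-hoc comparisons, correlation analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
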