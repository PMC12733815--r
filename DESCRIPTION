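Package: oystermetry
Title: Counting and Morphometry of Oysters in Top-Down Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for counting cultured oysters
    (Crassostrea virginica) and estimating their shell length and width from
    top-down photographs taken against a uniform blue background with a
    circular reference object of known diameter in frame. Segments the image
    with a hue-adaptive density-based pixel clustering (a modified DBSCAN
    with 8-neighbour distances, edge exclusion and a three-way pixel
    labelling), removes shadows, debris and the reference cap with a small
    multilayer-perceptron group classifier, recovers the millimetre scale
    from the reference circle via a circle Hough transform on the luma
    channel, measures each group's axis-aligned bounding box, and refines
    the result with a random-forest classifier that drops residual noise and
    splits fused pairs of oysters by halving their length. Includes a
    ground-truthed synthetic scene generator for training and validation,
    and a paired Wilcoxon signed-rank test for comparing per-image
    measurement variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
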