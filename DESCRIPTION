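Package: spncode
Title: Behavior Segmentation and Neural Encoding Analysis for Striatal
    Population Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how striatal projection neuron (SPN)
    populations encode spontaneous behavior in freely moving mice.
    Implements an unsupervised behavior-identification pipeline operating
    on pose-estimation output (posture features, replicated t-SNE
    embedding, Gaussian mixture clustering, Hamming-distance consensus,
    Wasserstein cluster merging, rule-based registration to a 12-behavior
    catalog, maximum-likelihood frame assignment, and episode
    post-processing); population-vector activation similarity with
    split-half, sliced, odd/even-frame and episode-alternating partitions
    and spatial-shuffle controls; behavior information (a mutual-information
    tuning statistic) with event-shuffle significance for detecting
    behavior-active cells; occurrence-based detection of behavior-silent
    and behavior-inactive cells; one-vs-one linear support vector machine
    decoding of behavior with a behavioral-distance reconstruction error
    and a time-lagged chance level; longitudinal cell-registration
    stability analyses; and a synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    mclust,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
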