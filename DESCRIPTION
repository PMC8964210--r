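Package: cytoswarm
Title: Swarm-Selected Fuzzy C-Means Classification of Cervical Cell Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid classification of segmented single-cell Pap smear images.
    Extracts thirteen nucleus/cytoplasm morphometric features plus a
    rotation-invariant binary-histogram-Fourier (BHF) texture block from
    labelled cell images with nucleus and cytoplasm masks, selects a reduced
    feature subset with a quantum-behaved binary swarm optimizer whose fitness
    is the macro-F1 score of a fuzzy C-means classifier on an internal
    validation split, and evaluates the resulting models with stratified
    splits, k-fold cross-validation, confusion-matrix metrics, Cohen's kappa
    and a membership mean-squared error. Includes a synthetic generator of
    seven-class cell images emulating dysplasia progression so the whole
    pipeline is testable without any image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    graphics
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
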