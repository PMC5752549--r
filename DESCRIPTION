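Package: seclass
Title: Sample-Expansion Deep Learning for Small-Sample Gene Expression Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor gene-expression classifiers for the small-n, high-p regime built on
    corruption-based sample expansion: each training profile is copied floor(m/a) times
    with disjoint groups of a gene values zeroed, and the corrupted copies are merged
    with the raw profiles to enlarge the training set. On top of the expansion the
    package implements, from scratch, a tied-weight stacked autoencoder with greedy
    layer-wise pretraining and softmax fine-tuning (SESAE) and a 1-dimensional
    convolutional network with valid convolutions, non-overlapping max pooling and
    delta-rule backpropagation (SE1DCNN), together with an Infinite Feature Selection
    gene-ranking stage, per-gene standardization, stratified repeated evaluation, and a
    synthetic expression-data generator so the whole pipeline is testable without
    external microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
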