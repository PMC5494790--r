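Package: selmeeg
Title: Three-Class Epileptic EEG Detection with Wavelet Features and Sparse
    Extreme Learning Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end system for classifying single-channel EEG segments
    into normal, interictal and ictal classes. Segments are band-limited to
    0-32 Hz, decomposed with a three-level lifting-scheme Daubechies-4 wavelet
    transform into delta/theta/alpha/beta subbands, and summarised by the
    maximum and standard deviation of each subband (an eight-dimensional
    feature vector per 512-sample epoch). Classification uses a sparse extreme
    learning machine (a kernel classifier trained by single-multiplier
    coordinate updates on a box-constrained dual quadratic programme, with no
    bias term), extended to three classes by one-against-all, one-against-one,
    directed-acyclic-graph, error-correcting-output-code and binary-tree
    strategies. Includes a Bonn-format text reader, a synthetic three-class
    EEG generator, k-fold cross-validation, kernel-parameter grid search and
    confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
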