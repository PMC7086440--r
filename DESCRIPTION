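Package: mtdgrn
Title: Multi-Time-Delay Gene Regulatory Network Inference by Fuzzy Label
    Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers gene regulatory networks with discrete per-edge time
    delays from short time-series expression data. Each gene pair at each
    candidate lag is described by three similarity measures (relative
    change trend score, lagged Pearson correlation, and binned mutual
    information) and classified as regulation versus no regulation by
    semisupervised fuzzy label propagation on a k-nearest-neighbour
    similarity graph, starting from a small set of seed-labelled pairs.
    Includes k-nearest-neighbour imputation of missing expression values,
    a ground-truthed synthetic generator of delayed linear regulatory
    networks, and confusion-matrix evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
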