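Package: stylebin
Title: Metagenome Binning with Genomic Style Features from a Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised genome binning of metagenomic contigs using "genomic
    style" features: Gram matrices of feature maps extracted from a small
    one-dimensional convolutional network pre-trained to classify bacterial
    species from one-hot encoded DNA windows. Provides the feature-extraction
    network (built and trained natively on BLAS matrix operations), per-layer
    style vectors with window averaging and optional coverage augmentation, a
    k-mer frequency baseline, Ward agglomerative binning, pair-counting and
    entropy-based clustering metrics (Rand index, adjusted Rand index,
    homogeneity, completeness, pair F-measure), and synthetic data generators
    (Markov species genomes and GC-content groups) so the whole pipeline is
    reproducible without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
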