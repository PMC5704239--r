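Package: barcodeCNN
Title: Taxonomic Classification of DNA Barcodes with a Character-Level
    Temporal Convolutional Network
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies DNA barcode sequences (e.g., COI markers from the
    Barcode of Life Data Systems) into taxonomic orders with a
    character-level one-dimensional convolutional neural network. Sequences
    over the alphabet {A,C,G,T,-} are optionally "3-1" encoded (each
    non-overlapping trinucleotide mapped to one of 125 dictionary symbols),
    one-hot quantized into fixed-length frames, and fed to a configurable
    stack of temporal convolution and max-pooling layers trained by
    mini-batch stochastic gradient descent. Includes FASTA/CSV readers for
    labelled barcode data, reproducible train/validation/test splitting,
    confusion-matrix evaluation with macro recall and precision, and a
    seeded synthetic-barcode generator with class-specific motifs so the
    full pipeline can be exercised without downloading reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    Rcpp,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Classification, Sequencing, Software
RoxygenNote: 7.3.3
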