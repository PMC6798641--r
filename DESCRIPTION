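Package: premirnet
Title: Pre-miRNA Hairpin Classification with a Convolutional Recurrent Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies precursor microRNA (pre-miRNA) hairpins from an RNA
    sequence and its dot-bracket secondary structure using a cascaded
    convolutional and bidirectional long short-term memory (BLSTM) network
    trained with focal loss to handle the strong class imbalance typical of
    pre-miRNA screens. Includes readers and writers for FASTA, RNAfold-style
    structure files and label manifests; a built-in Nussinov base-pair
    maximisation folder so no external folding binary is required; one-hot
    encoders for sequence and structure; the full network with batch
    normalisation, dropout and L2 regularisation implemented from first
    principles; stratified cross-validation with Adam optimisation; the
    standard sensitivity/specificity/PPV/F-score/g-mean/AUROC/AUPR metric
    suite; and a seeded synthetic hairpin generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
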