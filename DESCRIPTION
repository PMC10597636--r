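Package: accessfold
Title: Fast RNA Accessibility via an Exact Local-Folding Oracle and Neural Surrogates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes RNA accessibility, the free-energy cost (kcal/mol) for a
    fixed-length subregion of an RNA to be entirely unpaired in the Boltzmann
    ensemble of non-pseudoknotted secondary structures, under a maximal
    base-pair span constraint (local folding). Provides an exact dynamic
    programming oracle with an exhaustive-enumeration cross-check, two
    generators of artificial RNA training sequences (uniform-composition and
    planted-stem), trainable neural surrogate models (fully convolutional,
    U-Net and transformer architectures) that predict accessibility profiles
    directly from sequence, chunk-and-stitch prediction for sequences longer
    than the model maximum, evaluation metrics (normalised mean square error,
    Spearman rank correlation, protein-abundance correlation), and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
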