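Package: triple
Title: Base-Pairing Shannon Entropy Under a Stem-Constrained RNA Secondary
    Structure Ensemble
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes Shannon base-pairing entropies of RNA sequences under a
    constrained stochastic context-free grammar in which every stem carries at
    least three consecutive canonical base pairs, and scores how strongly the
    entropy separates a sequence from shuffled backgrounds via Z-scores.
    Includes maximum-entropy derivation of the grammar rule probabilities,
    inside-outside computation of base-pair probability matrices, mono- and
    di-nucleotide (Euler-path) shuffling null models, Kolmogorov-Smirnov
    normality checks of background entropies, and threshold summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
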