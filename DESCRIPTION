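Package: coremix
Title: Microbial Relative Abundance from Core-Genome Alignments by
    Collapsed Gibbs Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates relative abundances of microbial species from
    shotgun metagenomic reads aligned to concatenated core-genome
    reference sequences. Reads are modelled as draws from a finite
    mixture of per-species read-composition distributions with a
    Dirichlet prior on the mixture weights; the latent read-origin
    labels are integrated over by collapsed Gibbs sampling, and
    mixture weights are converted to length-corrected relative
    abundances. Includes a reference builder, a SAM alignment
    profiler, an exact-enumeration posterior oracle for small
    instances, a community and read simulator with an internal
    matcher for end-to-end validation, evaluation metrics, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
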