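Package: tcrhom
Title: Repertoire Homology Kernels and Mixed-Effects Score Tests for
    TCR CDR3 Association Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Association testing between a subject's T-cell receptor (TCR)
    CDR3 amino-acid repertoire and a clinical phenotype under a
    generalized linear mixed model.  Explicitly extracted features
    (amino-acid composition weighted by biochemical properties such as
    Kyte-Doolittle hydrophobicity) enter as fixed effects and are tested
    with a multivariate score statistic; hidden sequence features enter
    as a random effect whose covariance is an abundance-weighted
    best-match repertoire homology kernel built from pairwise global
    alignments under BLOSUM62 or PAM250, tested with a
    variance-component score statistic.  The two independent p-values
    are combined by Fisher's method.  Includes a CDR3 repertoire
    simulator for type-I-error and power studies and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
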