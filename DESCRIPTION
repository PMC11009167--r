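Package: treeclock
Title: Cell Lineage Tree-Shape Clocks from Single-Cell Somatic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds biological age predictors from the shape of somatic-mutation
    cell lineage trees. Starting from per-cell sparse alternative/reference UMI
    count matrices of single-nucleotide variants, the package removes germline
    and low-confidence calls, encodes cells as pseudo-alignments, infers rooted
    ultrametric trees with UPGMA on p-distances, computes a 31-metric catalogue
    of spectral, branch-length, imbalance and tip-distance tree statistics, and
    fits an elastic net age regression with grouped nested leave-one-out
    cross-validation, feature pre-selection, dummy baselines and external-cohort
    testing. A cohort simulator with age-scaled mutation accumulation and
    age-increasing clonal imbalance provides fully synthetic inputs so the whole
    pipeline runs without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    Biostrings,
    vcfR,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
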