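Package: mimland
Title: Genomic Landscapes of Diversity, Divergence and Introgression in a
    Monkeyflower Radiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based population-genomic analysis of a multi-taxon
    radiation: nucleotide diversity (pi), absolute divergence (dxy), and
    Kst-family differentiation (Fst) in sliding windows with per-pair
    missing-data denominators; neighbor-joining window trees with
    concordance scores and clade-recovery fractions; principal-component
    summaries of many landscapes with permutation tests for spatial
    autocorrelation; divergence-time trajectories of landscape/covariate
    correlations with a phylogenetic correction for pairwise data;
    ABBA-BABA introgression statistics (Patterson's D with weighted block
    jackknife, admixture proportion f, and window-based fd); a forward
    Wright-Fisher simulator of six genomic-landscape divergence scenarios;
    and a multispecies-coalescent generator of synthetic radiation data
    with exported ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph
Config/testthat/edition: 3
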