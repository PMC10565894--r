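Package: introscan
Title: Windowed Introgression Scans, Admixture Dating, and Haplotype
    Selection Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-based ABBA-BABA tests of introgression (Patterson's D
    with block-jackknife significance), the windowed admixture proportion f_d,
    invariant-site-aware nucleotide diversity and divergence (pi, d_xy, d_a),
    Hudson-type F_ST, a phylogenetically stratified "epoch scan" that dates
    admixture by varying the P1 taxon, selection-against-gene-flow diagnostics
    (f_d versus F_ST, pi and recombination-rate quantile bins), extended
    haplotype homozygosity, and infinite-sites haplotype networks. A compiled
    multispecies-coalescent simulator with admixture pulses and planted-sweep
    haplotype panels provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    emmeans,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
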