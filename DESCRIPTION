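Package: lakerad
Title: Population Genomics of Marine-Lake Sponges from ddRAD Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a marine-lake
    seascape-genomics workflow for the sponge Suberites diversicolor:
    coalescent simulation of founder-seeded lake metapopulations and ddRAD
    read generation; de novo RAD locus assembly (demultiplexing, trimming,
    greedy clustering, low-complexity masking, shared-reference construction,
    GC/k-mer contaminant screening, unique read assignment); genotype
    likelihoods with empirical-Bayes genotype calling and a coverage-by-
    missingness filter grid; diversity, differentiation (Hedrick-standardised
    G''ST), nested AMOVA, PCA, folded site-frequency spectra and relative
    migration networks; stairway-style piecewise-constant Ne inference; and
    seascape association tests (Mantel, Spearman) against geographic,
    environmental and tidal-connection distance matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    Biostrings,
    vcfR,
    geosphere,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
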