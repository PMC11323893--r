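Package: phagesv
Title: Ensemble Structural-Variant Merging and Genetic-Exchange Analysis
    for Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population-scale analysis of structural variation
    (SV) in bacteriophage genomes from long-read metagenomes. Merges
    per-sample, multi-caller SV callsets into a consensus set with a
    Cluster Affinity Search Technique (CAST) graph-clustering algorithm,
    builds a cohort-level nonredundant SV catalog, benchmarks callsets
    against truth sets, classifies SVs that show close homology to
    bacterial genomes (genetic-exchange-like SVs), scores gene codon-bias
    typicality with a Markov-chain index, infers horizontal gene transfer
    direction from cross-kingdom clade nesting in rooted gene trees,
    predicts phage hosts from CRISPR spacer matches, and computes cohort
    statistics (SV density, functional enrichment with FDR control,
    lifestyle comparisons, phage-bacteria sharing networks). Includes a
    synthetic-cohort generator that produces every pipeline input with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
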