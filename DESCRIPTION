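Package: glscape
Title: Correlated Genomic Landscapes from Haploid Genotype Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sliding-window population-genomic landscapes for haploid species
    sampled at low sequencing depth, without calling genotypes. From per-read
    pileup observations the package computes haploid genotype likelihoods,
    site-allele-frequency (SAF) likelihood vectors, maximum-likelihood folded
    one- and two-dimensional site-frequency spectra by expectation
    maximization, and empirical-Bayes per-window estimates of nucleotide
    diversity, Watterson's theta, Tajima's D and Reynolds-type weighted FST.
    Consensus alignments give between-species divergence (dXY) and
    neighbor-joining window trees scored against a species tree with the
    Robinson-Foulds partition metric. Landscape correlation across species is
    summarized by principal components, Spearman correlation structure with
    Benjamini-Hochberg adjustment, lagged spatial autocorrelation with a
    permutation null, Mantel tests, and a sympatric-allopatric differentiation
    contrast. A multispecies-coalescent simulator with gene-density-modulated
    local effective population size provides genome-scale test data with
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    geosphere,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
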