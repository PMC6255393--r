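Package: radpop
Title: Population Genomics of Adaptive Radiations with Gene Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of multi-species
    resequencing panels from rapid radiations: site-level variant
    filtration and callable-genome masks, nucleotide diversity and
    Hudson-style FST, outgroup polarization and derived-allele sharing
    depth, ABBA-BABA D statistics with block-bootstrap significance,
    windowed neighbor-joining tree sets (cloudograms) with subtree
    prevalence tests across chromosomes, a discrete-time Markov-chain
    coalescent model for a species trio with gene flow, F2 bin
    genotyping and recombination-rate estimation, and genome-wide
    covariate analyses (regressions with a chromosome contrast, partial
    Kendall correlation, Fisher enrichment, permutation tests). A
    synthetic-data generator emulating the statistical structure of
    such panels makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    jsonlite,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
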