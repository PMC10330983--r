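Package: sweepscan
Title: Selective-Sweep Scans from Windowed Diversity and Fst in Resequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering selective sweeps in multi-population
    resequencing data: hard-filtering and annotation of SNP variant tables,
    windowed nucleotide diversity (pi) and Hudson-style weighted Fst in
    sliding windows, joint empirical-tail selection of candidate windows,
    region merging and candidate-gene calling with cross-comparison sharing,
    population-structure summaries (allele-sharing distances, neighbor-joining
    trees, variance-standardized PCA), candidate-locus follow-up (allelic
    case-control tests, EM haplotype-frequency estimation, linkage
    disequilibrium and block delimitation), and hypergeometric gene-set
    over-representation with FDR control. A seeded Balding-Nichols simulator
    with implanted sweeps and genotype-driven phenotypes makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    vcfR,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
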