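Package: captureSNP
Title: Targeted Capture Resequencing SNP Analysis with Tumor-Normal Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for single-nucleotide polymorphism analysis of
    hybridization-capture resequencing experiments on matched tumor and leukocyte
    samples. Provides a capture-experiment simulator with known ground truth
    (reference, probe tiling, planted germline variants, tumor loss-of-heterozygosity
    events, paired-end reads), read quality filtering, exhaustive unique ungapped
    mapping with a mismatch budget, paired-end acceptance, target coverage and
    enrichment statistics, strand-split pileup construction, threshold-based diploid
    genotype calling with coverage-tier confidence, tumor-normal genotype-difference
    (loss-of-heterozygosity candidate) detection, variant-set overlap and Venn
    statistics, annotation against user-supplied dbSNP and GWAS-catalog snapshots,
    binary minor/major haplotype encoding, and cohort genotype frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    data.table,
    jsonlite,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    withr
Config/testthat/edition: 3
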