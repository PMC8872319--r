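Package: popsweep
Title: Genomic Diversity and Selective-Sweep Scans from Phased SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Windowed population-genetic diversity statistics and a composite
    selective-sweep scan for phased, biallelic diploid SNP genotypes. Provides
    VCF input/output and SNP quality control (minor allele frequency, call
    rate, exact Hardy-Weinberg test), windowed nucleotide diversity and
    Tajima's D, runs of homozygosity by the consecutive method with F_ROH,
    pairwise linkage disequilibrium with LD-decay profiling and LD-based
    historical effective population size, per-SNP integrated haplotype scores
    (EHH/iHH/iHS) with frequency-bin standardization, a de-correlated
    composite of multiple signals (DCMS) with robust (FAST-MCD) decorrelation
    and robust-normal significance calling, and annotation of significant
    windows against gene and QTL intervals. Includes a seeded synthetic-data
    generator (neutral site-frequency-spectrum sites, mosaic haplotypes with
    tunable LD decay, injectable sweeps, autozygous tracts, missingness) so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
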