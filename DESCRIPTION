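Package: gbspop
Title: Population Genomics Toolkit for Genotype-by-Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of genotype-by-sequencing (GBS) experiments on
    plant breeding populations: demultiplexing of barcoded Illumina lanes with
    adapter-tag trimming, a multi-sample VCF data model with merging of
    per-sample files, layered genotype/sample/site filters, summary and
    per-site diversity statistics (MAF, observed/expected heterozygosity,
    Hardy-Weinberg deviation, F-statistics over subpopulations), pairwise
    genotype comparison, haplotype-cluster hidden Markov model imputation for
    inbred lines, exporters towards distance, genetic-mapping and genomic
    selection tools, a Mendelian segregation based quality-assessment
    framework for F1 and MAGIC populations, and simulators that generate all
    of the above inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
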