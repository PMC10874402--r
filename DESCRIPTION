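Package: taslrs
Title: Downstream Interpretation of Targeted Adaptive-Sampling Long-Read
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis toolkit for targeted adaptive-sampling
    nanopore (long-read) sequencing of hereditary cancer gene panels:
    adaptive-sampling quality control (on/off-target depth, enrichment,
    N50), target-region BED construction from gene annotation,
    SNV/indel pathogenicity prioritization from annotated VCFs,
    structural-variant false-positive elimination and putative-pathogenic
    classification, mobile-element-insertion characterization (target
    site duplication, poly-A tail, 3' transduction, source locus,
    5' truncation), haplotype-resolved allele-specific methylation
    aberration calling against a control panel, and MAF-binned genotype
    concordance. Ships deterministic synthetic-fixture generators that
    emulate every input, with manifests of planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
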