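Package: scvaf
Title: Single-Cell Expressed Variant Allele Fraction and Allele-Specific
    Expression from Barcoded RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("scvaf", "developers", email = "scvaf@example.org", role = c("aut", "cre"))
Description: Estimates the expressed variant allele fraction (VAF_RNA) at
    heterozygous SNV loci from cell-barcoded, UMI-tagged single-cell RNA-seq
    alignments.  Performs per-cell barcoded pileup with UMI deduplication,
    pooled-count heterozygosity selection with variant-quality gates, cell
    quality control on a gene-by-cell count matrix, and classification of
    allelic patterns (strictly/predominantly monoallelic, bi-allelic, random
    monoallelic, skewed) at SNV and gene level across minimum read-depth
    (minR) thresholds, including an intronic versus non-intronic comparison.
    Ships a seeded synthetic-data generator that emulates 10x-style 3'
    scRNA-seq allele data with fully known ground truth, and a pipeline
    driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    methods,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
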