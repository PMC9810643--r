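Package: longATAC
Title: Chromatin Accessibility and Genetic Variation from Long-Read
    Single-Cell ATAC-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of long-read (nanopore-style) single-cell ATAC-seq
    fragments. From per-cell long-read alignments or fragment tables the
    package derives chromatin accessibility (Tn5 insertion-end peak
    calling, TSS enrichment, FRIP, footprints, species-mixing doublet
    detection, single-molecule co-accessibility of neighbouring peaks)
    and genetic variation (allele-specific peaks via flanking-SNP read
    haplotyping with FDR control, read-backed SNP phasing with switch
    error evaluation, multi-cell-supported structural variant calling,
    and per-cell copy-number profiles). A synthetic-data generator with
    a complete planted-truth ledger supports end-to-end validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    vcfR,
    Matrix,
    igraph,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
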