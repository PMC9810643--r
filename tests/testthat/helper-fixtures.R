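## Shared fixture builders: everything is generated in code at test time.

suppressPackageStartupMessages({
    library(GenomicRanges)
})

## quick fragment container from parallel vectors (1-based closed coords)
mkFrags <- function(chrom, start, end, cell = "cellA", mapq = 60L,
                    cigar = "", anchors = "", species = NA_character_,
                    seqlens = NULL) {
    n <- max(length(chrom), length(start), length(end))
    gr <- GRanges(rep(chrom, length.out = n),
                  IRanges(rep(start, length.out = n),
                          rep(end, length.out = n)),
                  cell = rep(cell, length.out = n),
                  mapq = rep(as.integer(mapq), length.out = n),
                  read_id = sprintf("r%05d", seq_len(n)),
                  cigar = rep(cigar, length.out = n),
                  anchors = rep(anchors, length.out = n),
                  species = rep(species, length.out = n))
    if (!is.null(seqlens)) seqlengths(gr) <- seqlens[seqlevels(gr)]
    ScFragments(gr)
}

## width-1 insertion ends at given positions
mkEnds <- function(chrom, pos, cell = "cellA", seqlens = NULL) {
    n <- length(pos)
    gr <- GRanges(rep(chrom, length.out = n), IRanges(pos, width = 1L),
                  cell = rep(cell, length.out = n),
                  read_id = sprintf("e%06d", seq_len(n)),
                  side = rep("left", n))
    if (!is.null(seqlens)) seqlengths(gr) <- seqlens[seqlevels(gr)]
    gr
}

## a small phased het SNP table
mkVariants <- function(chrom, pos, ref = "A", alt = "G",
                       hap1 = NULL, phased = TRUE) {
    n <- length(pos)
    ref <- rep(ref, length.out = n); alt <- rep(alt, length.out = n)
    if (is.null(hap1)) hap1 <- ref
    hap1 <- rep(hap1, length.out = n)
    data.frame(chrom = rep(chrom, length.out = n), pos = pos, ref = ref,
               alt = alt, hap1 = hap1,
               hap2 = ifelse(hap1 == ref, alt, ref),
               phased = rep(phased, length.out = n),
               phase_set = rep("ps1", n))
}

## minimal single-sample SAM text (needs samtools-free conversion through
## Rsamtools::asBam inside readFragments)
writeSamFixture <- function(path, records,
                            sq = c("chr1" = 1000000L,
                                   "chr9" = 1000000L,
                                   "chr22" = 1000000L)) {
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
    writeLines(c(hdr, records), path)
    path
}
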