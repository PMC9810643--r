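#' @import methods
#' @importFrom BiocGenerics sort start end width strand unlist
#'   start<- end<- strand<-
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges findOverlaps countOverlaps overlapsAny
#'   subsetByOverlaps reduce resize
#' @importFrom GenomicRanges GRanges granges
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#' @importFrom stats median p.adjust rbinom rlnorm rpois runif setNames
#'   binom.test ppois plnorm ecdf quantile rnorm cor
#' @importFrom utils head tail
NULL

## Required metadata columns of a fragment GRanges. `cell` identifies the
## single cell; `read_id` is unique per fragment; `cigar` ("" if absent)
## and `anchors` ("" or "chrom:pos:strand" entries joined by ";") carry the
## SV evidence of long-read alignments; `species` supports mixing designs.
.FRAG_MCOLS <- c("cell", "mapq", "read_id", "cigar", "anchors", "species")

#' Fragment container for long-read scATAC data
#'
#' An \code{ScFragments} object is a \linkS4class{GRanges} holding one range
#' per aligned long-read fragment, with per-fragment metadata columns
#' \code{cell}, \code{mapq}, \code{read_id}, \code{cigar} (SAM CIGAR string,
#' \code{""} when unavailable), \code{anchors} (split-alignment anchors of
#' supplementary alignments, \code{"chrom:pos:strand"} joined by \code{";"},
#' \code{""} if none) and \code{species} (label of the genome the fragment
#' aligned to; \code{NA} outside mixing experiments).
#'
#' @slot .Data inherited \code{GRanges} representation.
#' @export
setClass("ScFragments", contains = "GRanges")

setValidity("ScFragments", function(object) {
    msg <- character()
    miss <- setdiff(.FRAG_MCOLS, colnames(mcols(object)))
    if (length(miss))
        msg <- c(msg, paste("missing metadata column(s):",
                            paste(miss, collapse = ", ")))
    if (!length(msg) && length(object)) {
        if (anyNA(mcols(object)$cell))
            msg <- c(msg, "cell ids must not be NA")
        if (anyDuplicated(mcols(object)$read_id))
            msg <- c(msg, "read_id values must be unique")
        if (any(width(object) < 1L))
            msg <- c(msg, "fragments must have positive length")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ScFragments object
#'
#' @param gr A \code{GRanges} (1-based, closed intervals) with at least a
#'   \code{cell} metadata column. Missing optional columns are filled with
#'   defaults (\code{mapq = 60}, generated \code{read_id}, empty
#'   \code{cigar}/\code{anchors}, \code{NA} species).
#' @return An \code{ScFragments} object.
#' @export
ScFragments <- function(gr) {
    stopifnot(is(gr, "GRanges"))
    mc <- mcols(gr)
    if (is.null(mc$cell))
        stop("fragment GRanges needs a 'cell' metadata column")
    if (is.null(mc$mapq)) mc$mapq <- 60L
    if (is.null(mc$read_id)) mc$read_id <- sprintf("frag%08d", seq_along(gr))
    if (is.null(mc$cigar)) mc$cigar <- ""
    if (is.null(mc$anchors)) mc$anchors <- ""
    if (is.null(mc$species)) mc$species <- NA_character_
    mcols(gr) <- mc[, union(.FRAG_MCOLS, colnames(mc))]
    new("ScFragments", gr)
}

setMethod("show", "ScFragments", function(object) {
    ncell <- length(unique(mcols(object)$cell))
    cat("ScFragments with", length(object), "fragments from", ncell,
        "cells\n")
    if (length(object))
        cat("  median fragment length:", median(width(object)), "bp\n")
    callNextMethod()
})

#' @describeIn ScFragments Cell identifiers of each fragment.
#' @param x An \code{ScFragments} object.
#' @export
cellIds <- function(x) mcols(x)$cell

#' @describeIn ScFragments Fragment lengths in bp.
#' @export
fragmentLengths <- function(x) width(x)

#' Synthetic-experiment configuration
#'
#' Parameters of the synthetic long-read scATAC experiment generated by
#' \code{\link{simulateExperiment}}. Defaults reflect the data properties the
#' method is built around: fragment-length medians of roughly 4--4.9 kb and
#' per-cell read yields below the platform's ~10,000 reads/cell throughput
#' ceiling.
#'
#' @slot nCells number of single cells.
#' @slot chromLengths named integer vector of chromosome lengths (bp).
#' @slot nPeaks number of accessible peaks planted across the genome.
#' @slot peakWidthBp planted peak width (bp).
#' @slot fracAsp fraction of peaks planted as allele-specific.
#' @slot aspSkew P(maternal) for reads anchored in a planted ASP.
#' @slot fragMedianBp median of the log-normal fragment-length law (bp).
#' @slot fragSigma sdlog of the fragment-length law.
#' @slot readsPerCell fragments generated per cell.
#' @slot fracPeakReads fraction of reads whose left Tn5 end is anchored in a
#'   peak (the rest are uniform background).
#' @slot hetSnpPerBp density of planted heterozygous SNPs (SNPs/bp).
#' @slot baseError per-base probability that an observed SNP allele is
#'   flipped relative to the read's haplotype.
#' @slot plantedSvs data.frame(type, chrom, pos, length, chrom2, pos2,
#'   cellFraction) of planted structural variants (1-based pos).
#' @slot svPosJitterSd per-read breakpoint jitter sd (bp).
#' @slot svLenJitterRel per-read relative length jitter sd.
#' @slot plantedCnvs data.frame(chrom, start, end, cn, cellFraction) of
#'   planted copy-number segments (1-based closed).
#' @slot ploidy baseline copy number of unplanted regions.
#' @slot speciesMixing logical; assign cells alternately to two species.
#' @slot doubletFraction fraction of cells that are cross-species doublets.
#' @slot speciesNoise per-fragment species mislabel rate for singlets.
#' @slot coaccessPairs number of planted co-accessible peak pairs.
#' @slot coaccessGapRange range (bp) of planted pair centre distances.
#' @slot coaccessEnrichment fold enrichment of spanning molecules over the
#'   anchored-null expectation.
#' @slot seed integer RNG seed; fixed seed gives identical output.
#' @export
setClass("SimConfig", representation(
    nCells = "integer", chromLengths = "numeric", nPeaks = "integer",
    peakWidthBp = "integer", fracAsp = "numeric", aspSkew = "numeric",
    fragMedianBp = "numeric", fragSigma = "numeric", readsPerCell = "integer",
    fracPeakReads = "numeric", hetSnpPerBp = "numeric", baseError = "numeric",
    plantedSvs = "data.frame", svPosJitterSd = "numeric",
    svLenJitterRel = "numeric", plantedCnvs = "data.frame",
    ploidy = "numeric", speciesMixing = "logical", doubletFraction = "numeric",
    speciesNoise = "numeric", coaccessPairs = "integer",
    coaccessGapRange = "numeric", coaccessEnrichment = "numeric",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    fr <- c(fracAsp = object@fracAsp, aspSkew = object@aspSkew,
            fracPeakReads = object@fracPeakReads,
            doubletFraction = object@doubletFraction,
            baseError = object@baseError, speciesNoise = object@speciesNoise)
    bad <- names(fr)[fr < 0 | fr > 1]
    if (length(bad))
        msg <- c(msg, paste("fractions outside [0,1]:",
                            paste(bad, collapse = ", ")))
    if (object@fragMedianBp <= 0) msg <- c(msg, "fragMedianBp must be > 0")
    if (is.null(names(object@chromLengths)) ||
        any(!nzchar(names(object@chromLengths))))
        msg <- c(msg, "chromLengths must be a named vector")
    if (object@nPeaks > 0 &&
        object@peakWidthBp > max(object@chromLengths))
        msg <- c(msg, "peak width exceeds the longest chromosome")
    if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nCells,chromLengths,nPeaks,peakWidthBp,fracAsp,aspSkew See slots.
#' @param fragMedianBp,fragSigma,readsPerCell,fracPeakReads See slots.
#' @param hetSnpPerBp,baseError,plantedSvs,svPosJitterSd,svLenJitterRel
#'   See slots.
#' @param plantedCnvs,ploidy,speciesMixing,doubletFraction,speciesNoise
#'   See slots.
#' @param coaccessPairs,coaccessGapRange,coaccessEnrichment,seed See slots.
#' @return A validated \code{SimConfig}.
#' @export
simConfig <- function(nCells = 100L,
                      chromLengths = c(chr1 = 5e6, chr2 = 5e6),
                      nPeaks = 200L, peakWidthBp = 500L,
                      fracAsp = 0, aspSkew = 0.9,
                      fragMedianBp = 4500, fragSigma = 0.45,
                      readsPerCell = 2000L, fracPeakReads = 0.5,
                      hetSnpPerBp = 0, baseError = 0.02,
                      plantedSvs = emptySvTable(),
                      svPosJitterSd = 30, svLenJitterRel = 0.03,
                      plantedCnvs = emptyCnvTable(),
                      ploidy = 2, speciesMixing = FALSE,
                      doubletFraction = 0, speciesNoise = 0.005,
                      coaccessPairs = 0L,
                      coaccessGapRange = c(2000, 8000),
                      coaccessEnrichment = 3, seed = 1L) {
    new("SimConfig", nCells = as.integer(nCells),
        chromLengths = chromLengths, nPeaks = as.integer(nPeaks),
        peakWidthBp = as.integer(peakWidthBp), fracAsp = fracAsp,
        aspSkew = aspSkew, fragMedianBp = fragMedianBp,
        fragSigma = fragSigma, readsPerCell = as.integer(readsPerCell),
        fracPeakReads = fracPeakReads, hetSnpPerBp = hetSnpPerBp,
        baseError = baseError, plantedSvs = plantedSvs,
        svPosJitterSd = svPosJitterSd, svLenJitterRel = svLenJitterRel,
        plantedCnvs = plantedCnvs, ploidy = ploidy,
        speciesMixing = speciesMixing, doubletFraction = doubletFraction,
        speciesNoise = speciesNoise, coaccessPairs = as.integer(coaccessPairs),
        coaccessGapRange = coaccessGapRange,
        coaccessEnrichment = coaccessEnrichment, seed = as.integer(seed))
}

#' @rdname SimConfig-class
#' @export
emptySvTable <- function()
    data.frame(type = character(), chrom = character(), pos = integer(),
               length = integer(), chrom2 = character(), pos2 = integer(),
               cellFraction = numeric())

#' @rdname SimConfig-class
#' @export
emptyCnvTable <- function()
    data.frame(chrom = character(), start = integer(), end = integer(),
               cn = numeric(), cellFraction = numeric())

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nCells, "cells x", object@readsPerCell,
        "reads;", length(object@chromLengths), "chromosome(s),",
        object@nPeaks, "peaks\n")
    cat("  fragment length ~ logNormal(median", object@fragMedianBp,
        "bp, sigma", object@fragSigma, "); seed", object@seed, "\n")
})

#' Planted ground truth of a synthetic experiment
#'
#' Emitted by \code{\link{simulateExperiment}} alongside the fragments;
#' the acceptance surface every downstream stage is validated against.
#'
#' @slot peaks GRanges of planted peaks with columns \code{name},
#'   \code{isAsp}, \code{aspSkew}, \code{aspDirection}.
#' @slot variants data.frame of planted het SNPs (chrom, pos 1-based, ref,
#'   alt, hap1, hap2, phased, phase_set).
#' @slot svEvents data.frame of planted SVs plus \code{cells}
#'   (comma-separated carrier cell ids).
#' @slot cnvSegments data.frame of planted CN segments plus \code{cells}.
#' @slot doubletCells character vector of planted doublet cell ids.
#' @slot readHaplotypes data.frame(read_id, hap) with hap in
#'   \code{c("hap1","hap2")}; hap1 is the maternal haplotype.
#' @slot coaccessPairs data.frame of planted co-accessible pairs
#'   (peakA, peakB, distance, extraReads).
#' @export
setClass("SimTruth", representation(
    peaks = "GRanges", variants = "data.frame", svEvents = "data.frame",
    cnvSegments = "data.frame", doubletCells = "character",
    readHaplotypes = "data.frame", coaccessPairs = "data.frame"))

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", length(object@peaks), "peaks (",
        sum(mcols(object@peaks)$isAsp), "ASPs),",
        nrow(object@variants), "het SNPs,", nrow(object@svEvents),
        "SVs,", nrow(object@cnvSegments), "CNV segments,",
        length(object@doubletCells), "doublets,",
        nrow(object@coaccessPairs), "co-accessible pairs\n")
})

#' @rdname SimTruth-class
#' @param x A \code{SimTruth}.
#' @export
truthPeaks <- function(x) x@peaks

#' @rdname SimTruth-class
#' @export
truthVariants <- function(x) x@variants

#' @rdname SimTruth-class
#' @export
truthSvs <- function(x) x@svEvents

#' @rdname SimTruth-class
#' @export
truthCnvs <- function(x) x@cnvSegments

#' @rdname SimTruth-class
#' @export
truthDoublets <- function(x) x@doubletCells

#' @rdname SimTruth-class
#' @export
truthReadHaplotypes <- function(x) x@readHaplotypes

#' @rdname SimTruth-class
#' @export
truthCoaccessPairs <- function(x) x@coaccessPairs
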