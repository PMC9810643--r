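## Per-cell and aggregate library quality: TSS enrichment, footprints,
## FRIP, fragment counts and species-mixing doublet classification.

#' TSS enrichment profile and score
#'
#' Aggregates insertion-end counts in bins over a window around annotated
#' transcription start sites, oriented by gene strand (upstream left). The
#' scalar score divides the centre-bin count by the mean of the outermost
#' 10\% of bins on each side (ENCODE-style background normalisation).
#'
#' @param ends Width-1 \code{GRanges} of Tn5 insertion ends
#'   (\code{\link{fragmentEnds}}).
#' @param tss \code{GRanges} of TSS positions with strand (\code{*} treated
#'   as \code{+}).
#' @param flankBp Half-window around each TSS (default 2000); must be a
#'   multiple of \code{binBp}.
#' @param binBp Bin width (default 10).
#' @return List with \code{profile} (named vector of per-bin end counts,
#'   names = bin-centre offsets), \code{score} (NaN when no ends fall in
#'   the window, \code{Inf} when the outer flanks are empty but the centre
#'   is not) and \code{n_ends} used.
#' @export
tssEnrichment <- function(ends, tss, flankBp = 2000L, binBp = 10L) {
    stopifnot(length(tss) > 0L, flankBp %% binBp == 0L)
    prof <- .profileAround(ends, tss, flankBp, binBp,
                           stranded = TRUE)
    nb <- length(prof)
    nOuter <- max(1L, floor(0.1 * nb / 2))
    outer <- c(head(prof, nOuter), tail(prof, nOuter))
    centre <- prof[.centreBin(nb)]
    score <- if (sum(prof) == 0) {
        warning("no insertion ends within TSS flanks; score undefined")
        NaN
    } else if (mean(outer) == 0) Inf
    else as.numeric(centre / mean(outer))
    list(profile = prof, score = score, n_ends = sum(prof))
}

#' Footprint profile around bound sites
#'
#' Unstranded aggregate of insertion-end counts around site centres
#' (e.g. CTCF-bound sites); protein binding shows as a central dip.
#'
#' @inheritParams tssEnrichment
#' @param sites \code{GRanges} of site centres.
#' @return Named numeric vector of per-bin end counts.
#' @export
footprintProfile <- function(ends, sites, flankBp = 2000L, binBp = 10L) {
    stopifnot(length(sites) > 0L, flankBp %% binBp == 0L)
    .profileAround(ends, sites, flankBp, binBp, stranded = FALSE)
}

## bins of exactly binBp over [-flank, flank); the bin starting at offset 0
## (index nb/2 + 1) is the centre bin
.profileAround <- function(ends, sites, flankBp, binBp, stranded) {
    centre <- start(resize(granges(sites), width = 1L, fix = "center"))
    win <- GRanges(seqnames(sites),
                   IRanges(pmax(centre - flankBp, 1L),
                           centre + flankBp - 1L))
    ov <- findOverlaps(ends, win)
    off <- start(ends)[S4Vectors::queryHits(ov)] -
        centre[S4Vectors::subjectHits(ov)]
    if (stranded) {
        neg <- as.character(strand(sites))[S4Vectors::subjectHits(ov)] == "-"
        off[neg] <- -off[neg] - 1L     # keep the offset inside [-f, f)
    }
    nb <- 2L * (flankBp %/% binBp)
    bin <- (off + flankBp) %/% binBp + 1L
    prof <- tabulate(bin[bin >= 1L & bin <= nb], nbins = nb)
    names(prof) <- seq(-flankBp, flankBp - binBp, by = binBp) +
        binBp %/% 2L
    prof
}

.centreBin <- function(nb) nb %/% 2L + 1L

#' Fraction of read ends in peaks (FRIP)
#'
#' @param ends Width-1 \code{GRanges} of insertion ends.
#' @param peaks \code{GRanges} of (merged) peaks.
#' @return Fraction of ends inside any peak; NaN for zero ends.
#' @export
frip <- function(ends, peaks) {
    if (length(ends) == 0L) return(NaN)
    mean(overlapsAny(ends, reduce(granges(peaks))))
}

#' Classify species-mixing doublets
#'
#' In a barnyard design each fragment is labelled by the genome it aligned
#' to; a cell is called a doublet when its minor-species fraction exceeds
#' \code{minMinorFraction}.
#'
#' @param frags \code{\link{ScFragments}} with a non-NA \code{species}
#'   column.
#' @param minMinorFraction Doublet threshold on the minor-species fraction
#'   (default 0.1).
#' @return data.frame per cell: \code{cell, n_fragments}, one
#'   \code{frac_<species>} column per species, \code{minor_fraction},
#'   \code{is_doublet}. Cells with zero fragments are absent (warned).
#' @export
classifyDoublets <- function(frags, minMinorFraction = 0.1) {
    sp <- mcols(frags)$species
    if (all(is.na(sp))) stop("fragments carry no species labels")
    keep <- !is.na(sp)
    if (!all(keep)) warning(sum(!keep), " fragments without species label ",
                            "ignored")
    tab <- table(cell = mcols(frags)$cell[keep], species = sp[keep])
    frac <- prop.table(tab, margin = 1L)
    minor <- 1 - apply(frac, 1L, max)
    out <- data.frame(cell = rownames(tab),
                      n_fragments = as.integer(rowSums(tab)),
                      row.names = NULL)
    for (s in colnames(frac)) out[[paste0("frac_", s)]] <- as.numeric(frac[, s])
    out$minor_fraction <- as.numeric(minor)
    out$is_doublet <- out$minor_fraction > minMinorFraction
    out
}

#' Per-cell QC table
#'
#' Combines fragment counts, FRIP and TSS enrichment per cell (and doublet
#' flags when species labels are present).
#'
#' @param frags \code{\link{ScFragments}}.
#' @param peaks \code{GRanges} of peaks (for FRIP); may be NULL.
#' @param tss \code{GRanges} of TSS (for the enrichment score); may be
#'   NULL.
#' @param shiftPlus,shiftMinus Tn5 offsets for \code{\link{fragmentEnds}}.
#' @param minMinorFraction Doublet threshold, used when species labels are
#'   available.
#' @return data.frame with one row per cell.
#' @export
cellQc <- function(frags, peaks = NULL, tss = NULL,
                   shiftPlus = 4L, shiftMinus = 5L,
                   minMinorFraction = 0.1) {
    ends <- fragmentEnds(frags, shiftPlus, shiftMinus)
    cellsOf <- mcols(ends)$cell
    cells <- sort(unique(mcols(frags)$cell))
    out <- data.frame(cell = cells,
                      n_fragments = as.integer(
                          table(mcols(frags)$cell)[cells]))
    if (!is.null(peaks)) {
        inPk <- overlapsAny(ends, reduce(granges(peaks)))
        out$frip <- as.numeric(tapply(inPk, cellsOf, mean)[cells])
    }
    if (!is.null(tss)) {
        out$tss_enrichment <- vapply(cells, function(cl)
            suppressWarnings(
                tssEnrichment(ends[cellsOf == cl], tss)$score),
            numeric(1))
    }
    if (!all(is.na(mcols(frags)$species))) {
        db <- classifyDoublets(frags, minMinorFraction)
        out <- merge(out, db[, c("cell", "minor_fraction", "is_doublet")],
                     by = "cell", all.x = TRUE, sort = TRUE)
    }
    out
}
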