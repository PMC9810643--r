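## Per-cell copy-number profiles from binned fragment counts.

#' Binned per-cell fragment counts
#'
#' Bins tile each chromosome (last bin truncated); a fragment is assigned
#' to the bin containing its midpoint, so long fragments spanning a bin
#' edge are never double-counted. The count matrix conserves the total
#' fragment number.
#'
#' @param frags \code{\link{ScFragments}}; chromosome lengths from
#'   \code{seqlengths} (falling back to the largest end observed).
#' @param binBp Bin width (default 1e6; the method targets large-scale
#'   events).
#' @return List: \code{bins} (\code{GRanges}) and \code{counts} (matrix,
#'   cells x bins).
#' @export
binCounts <- function(frags, binBp = 1e6) {
    chroms <- seqlevels(frags)
    sl <- seqlengths(frags)
    obs <- tapply(end(frags), factor(as.character(seqnames(frags)),
                                     levels = chroms), max)
    sl[is.na(sl)] <- obs[is.na(sl)]
    binsL <- lapply(chroms, function(ch) {
        s <- seq.int(1L, sl[[ch]], by = binBp)
        GRanges(ch, IRanges(s, pmin(s + binBp - 1L, sl[[ch]])))
    })
    bins <- unlist(GenomicRanges::GRangesList(binsL), use.names = FALSE)
    mid <- GRanges(seqnames(frags),
                   IRanges((start(frags) + end(frags)) %/% 2L, width = 1L))
    bi <- findOverlaps(mid, bins, select = "first")
    cells <- sort(unique(mcols(frags)$cell))
    counts <- matrix(0L, nrow = length(cells), ncol = length(bins),
                     dimnames = list(cells, NULL))
    tab <- table(factor(mcols(frags)$cell, levels = cells), bi)
    counts[, as.integer(colnames(tab))] <- as.integer(tab)
    list(bins = bins, counts = counts)
}

#' Normalised per-cell copy-number profiles
#'
#' Depth of cell i in bin j is \code{raw_ij / total_i / ref_j}, rescaled so
#' each cell's autosomal median equals \code{ploidy}; integer copy number
#' rounds half away from zero. The per-bin reference \code{ref_j} removes
#' bin-specific rate differences: by default the median across cells of the
#' cells' depth-normalised counts (which requires >= 10 cells and cancels
#' events shared by all of them); a \code{"uniform"} reference
#' (proportional to bin width) or a numeric per-bin vector may be supplied
#' instead, e.g. when every cell carries the event of interest. Bins with a
#' zero reference are masked.
#'
#' @param bc \code{\link{binCounts}} output.
#' @param reference \code{"median"}, \code{"uniform"}, or a numeric vector
#'   of per-bin reference weights.
#' @param ploidy Baseline copy number (default 2; use 1 for haploid
#'   lines).
#' @return List: \code{bins}, \code{depth} (continuous), \code{cn}
#'   (integer), \code{mask} (usable bins), \code{reference}.
#' @export
normalizeCnv <- function(bc, reference = "median", ploidy = 2) {
    counts <- bc$counts; bins <- bc$bins
    tot <- rowSums(counts)
    rate <- counts / tot
    if (is.character(reference) && reference == "median") {
        if (nrow(counts) < 10L)
            stop("median reference needs >= 10 cells; supply an external ",
                 "reference instead")
        ref <- apply(rate, 2L, median)
    } else if (is.character(reference) && reference == "uniform") {
        ref <- width(bins) / sum(as.numeric(width(bins)))
    } else {
        ref <- as.numeric(reference)
        stopifnot(length(ref) == length(bins))
    }
    mask <- ref > 0
    if (any(!mask)) warning(sum(!mask), " bin(s) with zero reference masked")
    depth <- rate
    depth[, mask] <- sweep(rate[, mask, drop = FALSE], 2L, ref[mask], "/")
    depth[, !mask] <- NA_real_
    auto <- !(as.character(seqnames(bins)) %in%
              c("chrX", "chrY", "X", "Y")) & mask
    scale <- ploidy / apply(depth[, auto, drop = FALSE], 1L, median,
                            na.rm = TRUE)
    depth <- depth * scale
    cn <- floor(abs(depth) + 0.5) * sign(depth)   # round half away from 0
    list(bins = bins, depth = depth, cn = cn, mask = mask,
         reference = ref)
}

#' Aggregate copy-number profiles over cell groups
#'
#' Per-bin mean normalised depth per group, with the consensus integer
#' copy number as its rounded value; empty groups are skipped with a
#' warning. Cell order within a group does not affect the result.
#'
#' @param norm \code{\link{normalizeCnv}} output.
#' @param groups Named list of cell-id vectors partitioning the cells.
#' @return List: \code{bins}, \code{depth} (groups x bins),
#'   \code{consensus} (integer matrix).
#' @export
aggregateCnv <- function(norm, groups) {
    cells <- rownames(norm$depth)
    keep <- vapply(groups, function(g) sum(cells %in% g) > 0L, TRUE)
    if (any(!keep)) warning("empty group(s) skipped: ",
                            paste(names(groups)[!keep], collapse = ", "))
    groups <- groups[keep]
    depth <- t(vapply(groups, function(g)
        colMeans(norm$depth[cells %in% g, , drop = FALSE]),
        numeric(ncol(norm$depth))))
    rownames(depth) <- names(groups)
    list(bins = norm$bins, depth = depth,
         consensus = floor(abs(depth) + 0.5) * sign(depth))
}
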