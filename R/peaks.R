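## Peak calling from Tn5 insertion-end density (local-lambda Poisson
## caller), peak-set comparison, cCRE-style benchmarking, category
## annotation, and per-cell count matrices.

#' Peak-caller parameters
#'
#' Sliding-window Poisson caller settings. Windows of \code{windowBp}
#' advance by \code{stepBp}; each window's expected end count is
#' \code{max(genome-wide rate, local rate in localBgBp) * windowBp} and
#' significance is the Poisson upper tail.
#'
#' @param windowBp Window width (default 500).
#' @param stepBp Step between windows (default 100; must be <= window).
#' @param localBgBp Local background span centred on the window
#'   (default 10000; must exceed the window).
#' @param minEnds Minimum ends in a window (default 5).
#' @param pThreshold Poisson tail p-value cutoff (default 1e-5).
#' @param mergeGapBp Merge called windows closer than this (default 100).
#' @return A validated list of class \code{PeakCallParams}.
#' @export
peakCallParams <- function(windowBp = 500L, stepBp = 100L,
                           localBgBp = 10000L, minEnds = 5L,
                           pThreshold = 1e-5, mergeGapBp = 100L) {
    stopifnot(stepBp <= windowBp, localBgBp > windowBp,
              pThreshold > 0, pThreshold <= 1)
    structure(list(windowBp = as.integer(windowBp),
                   stepBp = as.integer(stepBp),
                   localBgBp = as.integer(localBgBp),
                   minEnds = as.integer(minEnds),
                   pThreshold = pThreshold,
                   mergeGapBp = as.integer(mergeGapBp)),
              class = "PeakCallParams")
}

#' Call accessibility peaks from insertion ends
#'
#' Scores sliding windows by the Poisson upper tail P(X >= k) with a local
#' or genome-wide background rate (whichever is larger), keeps windows with
#' at least \code{minEnds} ends and p <= \code{pThreshold}, and merges
#' windows closer than \code{mergeGapBp}. Deterministic; called peaks are
#' disjoint and sorted.
#'
#' @param ends Width-1 \code{GRanges} of insertion ends; chromosome lengths
#'   are taken from \code{seqlengths} (falling back to the largest observed
#'   position).
#' @param params \code{\link{peakCallParams}}.
#' @return \code{GRanges} of peaks with \code{name} and \code{score}
#'   (max -log10 p over merged windows).
#' @export
callPeaks <- function(ends, params = peakCallParams()) {
    if (length(ends) == 0L) return(GRanges())
    chroms <- unique(as.character(seqnames(ends)))
    sl <- seqlengths(ends)[chroms]
    obsMax <- tapply(start(ends), as.character(seqnames(ends)), max)
    sl[is.na(sl)] <- obsMax[names(sl)[is.na(sl)]]
    genomeLen <- sum(as.numeric(sl))
    globalRate <- length(ends) / genomeLen
    w <- params$windowBp
    kept <- list(); keptP <- list()
    for (ch in chroms) {
        pos <- sort(start(ends)[as.character(seqnames(ends)) == ch])
        starts <- seq.int(1L, max(1L, sl[[ch]] - w + 1L), by = params$stepBp)
        ## counts in [s, s+w-1] via binary search on sorted positions
        k <- findInterval(starts + w - 1L, pos) - findInterval(starts - 1L, pos)
        cand <- which(k >= params$minEnds)
        if (!length(cand)) next
        mid <- starts[cand] + w %/% 2L
        half <- params$localBgBp %/% 2L
        kLoc <- findInterval(pmin(mid + half, sl[[ch]]), pos) -
            findInterval(pmax(mid - half, 0L), pos)
        span <- pmin(mid + half, sl[[ch]]) - pmax(mid - half, 0L)
        lambda <- pmax(globalRate, kLoc / span) * w
        p <- ppois(k[cand] - 1L, lambda, lower.tail = FALSE)
        sig <- p <= params$pThreshold
        if (!any(sig)) next
        kept[[ch]] <- GRanges(ch, IRanges(starts[cand][sig],
                                          width = w))
        keptP[[ch]] <- p[sig]
    }
    if (!length(kept)) return(GRanges())
    win <- unlist(GenomicRanges::GRangesList(kept), use.names = FALSE)
    pall <- unlist(keptP, use.names = FALSE)
    merged <- reduce(win, min.gapwidth = params$mergeGapBp + 1L)
    ov <- findOverlaps(win, merged)
    score <- tapply(-log10(pmax(pall[S4Vectors::queryHits(ov)],
                                .Machine$double.xmin)),
                    S4Vectors::subjectHits(ov), max)
    mcols(merged)$name <- sprintf("peak%05d", seq_along(merged))
    mcols(merged)$score <- as.numeric(score)
    seqlengths(merged) <- sl[seqlevels(merged)]
    sort(merged)
}

#' Reciprocal overlap of two peak sets
#'
#' A peak "overlaps" when it intersects any peak of the other set by at
#' least \code{minBp}; counts and fractions are reported asymmetrically for
#' both sets.
#'
#' @param a,b Merged \code{GRanges} peak sets.
#' @param minBp Minimum intersection width (default 1).
#' @return List \code{(n_overlap_a, frac_a, n_overlap_b, frac_b)}.
#' @export
peakOverlap <- function(a, b, minBp = 1L) {
    na <- sum(overlapsAny(a, b, minoverlap = minBp))
    nb <- sum(overlapsAny(b, a, minoverlap = minBp))
    list(n_overlap_a = na,
         frac_a = if (length(a)) na / length(a) else 0,
         n_overlap_b = nb,
         frac_b = if (length(b)) nb / length(b) else 0)
}

#' Benchmark called peaks against a reference element set
#'
#' @param called \code{GRanges} of called peaks.
#' @param reference \code{GRanges} of reference elements (e.g. a cCRE
#'   catalogue); must be non-empty.
#' @param minBp Minimum intersection width.
#' @return List with \code{precision} (called peaks hitting a reference
#'   element) and \code{recall} (reference elements hit by a peak).
#' @export
benchmarkPeaks <- function(called, reference, minBp = 1L) {
    if (length(reference) == 0L) stop("empty reference set")
    list(precision = if (length(called))
             mean(overlapsAny(called, reference, minoverlap = minBp))
         else NaN,
         recall = mean(overlapsAny(reference, called, minoverlap = minBp)))
}

#' Annotate peaks by reference categories
#'
#' Assigns each peak the first overlapping category in \code{priority}
#' order (the cCRE-style order PLS > pELS > dELS > CTCF-only >
#' DNase-H3K4me3 by default); peaks hitting none are "unannotated".
#'
#' @param called \code{GRanges} of peaks.
#' @param reference \code{GRanges} with a \code{category} metadata column.
#' @param priority Character vector ordering categories; categories absent
#'   from it rank after it, alphabetically.
#' @return data.frame \code{(category, n, fraction)}; fractions sum to 1.
#' @export
annotatePeaks <- function(called, reference,
                          priority = c("PLS", "pELS", "dELS", "CTCF-only",
                                       "DNase-H3K4me3")) {
    cats <- unique(mcols(reference)$category)
    rank <- match(cats, priority)
    rank[is.na(rank)] <- length(priority) + rank(cats[is.na(rank)])
    ord <- cats[order(rank)]
    assigned <- rep("unannotated", length(called))
    ov <- findOverlaps(called, reference)
    if (length(ov)) {
        hitCat <- mcols(reference)$category[S4Vectors::subjectHits(ov)]
        hitRank <- match(hitCat, ord)
        best <- tapply(hitRank, S4Vectors::queryHits(ov), min)
        assigned[as.integer(names(best))] <- ord[best]
    }
    lev <- c(ord, "unannotated")
    n <- table(factor(assigned, levels = lev))
    data.frame(category = lev, n = as.integer(n),
               fraction = as.numeric(n) / max(1L, length(called)),
               row.names = NULL)
}

#' Cells-by-peaks insertion-end count matrix
#'
#' @param frags \code{\link{ScFragments}}.
#' @param peaks \code{GRanges} of peaks (a \code{name} column is used for
#'   column names).
#' @param shiftPlus,shiftMinus Tn5 offsets.
#' @return Sparse \code{dgCMatrix}, cells x peaks, of end counts.
#' @export
peakCellMatrix <- function(frags, peaks, shiftPlus = 4L, shiftMinus = 5L) {
    ends <- fragmentEnds(frags, shiftPlus, shiftMinus)
    cells <- sort(unique(mcols(frags)$cell))
    ov <- findOverlaps(ends, peaks)
    ci <- match(mcols(ends)$cell[S4Vectors::queryHits(ov)], cells)
    pj <- S4Vectors::subjectHits(ov)
    pn <- mcols(peaks)$name
    if (is.null(pn)) pn <- sprintf("peak%05d", seq_along(peaks))
    Matrix::sparseMatrix(i = ci, j = pj, x = 1,
                         dims = c(length(cells), length(peaks)),
                         dimnames = list(cells, pn))
}

#' Cells-by-genes accessibility score matrix
#'
#' Counts insertion ends in each gene body extended upstream by
#' \code{upstreamBp} (strand-aware), a simple gene accessibility score.
#'
#' @param frags \code{\link{ScFragments}}.
#' @param genes \code{GRanges} with strand and a \code{name} column.
#' @param upstreamBp Upstream extension (default 2000).
#' @param shiftPlus,shiftMinus Tn5 offsets.
#' @return Sparse matrix, cells x genes.
#' @export
geneScore <- function(frags, genes, upstreamBp = 2000L,
                      shiftPlus = 4L, shiftMinus = 5L) {
    neg <- as.character(strand(genes)) == "-"
    ext <- granges(genes)
    start(ext)[!neg] <- pmax(1L, start(ext)[!neg] - upstreamBp)
    end(ext)[neg] <- end(ext)[neg] + upstreamBp
    mcols(ext)$name <- mcols(genes)$name
    peakCellMatrix(frags, ext, shiftPlus, shiftMinus)
}
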