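## Single-molecule co-accessibility: neighbouring peak pairs supported by
## individual long fragments with one Tn5 end in each peak, tested against
## the fragment-length-distribution background.
##
## The statistic: for a pair (A left of B), observed = number of fragments
## whose left end lies in A and right end in B; expected = sum over
## A-anchored fragments of F(B.end - e) - F(B.start - e), F the empirical
## fragment-length CDF; the p-value is the Poisson upper tail, BH-corrected
## across candidate pairs. This conditions on where left ends actually
## fall, so the null is "fragment lengths are exchangeable across the
## genome".

#' Local median read length
#'
#' Median length of fragments whose midpoint falls within
#' \code{windowBp/2} of each locus; loci with fewer than 20 such fragments
#' fall back to the global median.
#'
#' @param frags \code{\link{ScFragments}}.
#' @param loci \code{GRanges} of loci (width-1 positions or regions; the
#'   midpoint is used).
#' @param windowBp Window width around each locus (default 1e5).
#' @param minFragments Fallback threshold (default 20).
#' @return Numeric vector of medians, one per locus.
#' @export
localMedianReadLength <- function(frags, loci, windowBp = 1e5,
                                  minFragments = 20L) {
    globalMed <- median(width(frags))
    if (!length(loci)) return(numeric())
    mid <- GRanges(seqnames(frags),
                   IRanges((start(frags) + end(frags)) %/% 2L, width = 1L))
    ctr <- resize(granges(loci), width = 1L, fix = "center")
    win <- suppressWarnings(resize(ctr, width = windowBp, fix = "center"))
    start(win) <- pmax(start(win), 1L)
    ov <- findOverlaps(mid, win)
    lens <- split(width(frags)[S4Vectors::queryHits(ov)],
                  factor(S4Vectors::subjectHits(ov),
                         levels = seq_along(loci)))
    vapply(lens, function(v)
        if (length(v) >= minFragments) median(v) else globalMed,
        numeric(1))
}

#' Candidate co-accessible peak pairs
#'
#' All same-chromosome, non-overlapping peak pairs whose centre distance d
#' satisfies 0 < d <= 2 x the local median read length at the pair
#' midpoint.
#'
#' @param peaks Sorted \code{GRanges} of peaks with a \code{name} column.
#' @param frags \code{\link{ScFragments}} (for the local read-length
#'   medians).
#' @param windowBp Local-median window (default 1e5).
#' @return data.frame \code{(peakA, peakB, iA, iB, distance,
#'   local_median)}; A is always the left peak.
#' @export
coaccessCandidatePairs <- function(peaks, frags, windowBp = 1e5) {
    peaks <- sort(peaks)
    pn <- mcols(peaks)$name
    if (is.null(pn)) pn <- sprintf("peak%05d", seq_along(peaks))
    cap <- 2 * max(width(frags))
    ctr <- start(peaks) + (width(peaks) - 1L) %/% 2L
    chrs <- as.character(seqnames(peaks))
    cand <- list()
    for (i in seq_along(peaks)) {
        j <- i + 1L
        while (j <= length(peaks) && chrs[j] == chrs[i] &&
               ctr[j] - ctr[i] <= cap) {
            if (start(peaks)[j] > end(peaks)[i])   # non-overlap, d > 0
                cand[[length(cand) + 1L]] <- c(i, j, ctr[j] - ctr[i])
            j <- j + 1L
        }
    }
    if (!length(cand))
        return(data.frame(peakA = character(), peakB = character(),
                          iA = integer(), iB = integer(),
                          distance = integer(), local_median = numeric()))
    cand <- do.call(rbind, cand)
    midLoci <- GRanges(chrs[cand[, 1L]],
                       IRanges((ctr[cand[, 1L]] + ctr[cand[, 2L]]) %/% 2L,
                               width = 1L))
    locMed <- localMedianReadLength(frags, midLoci, windowBp)
    keep <- cand[, 3L] <= 2 * locMed
    data.frame(peakA = pn[cand[keep, 1L]], peakB = pn[cand[keep, 2L]],
               iA = cand[keep, 1L], iB = cand[keep, 2L],
               distance = cand[keep, 3L], local_median = locMed[keep],
               row.names = NULL)
}

#' Test candidate pairs for single-molecule co-accessibility
#'
#' @param pairs \code{\link{coaccessCandidatePairs}} output.
#' @param peaks The same peak set (sorted).
#' @param frags \code{\link{ScFragments}}.
#' @param padBp Peak padding when matching fragment termini (default 0:
#'   the end must fall strictly inside the peak).
#' @param fdr BH FDR level annotated on the result (default 0.05).
#' @param lengthCdf Optional empirical fragment-length CDF (a function, as
#'   from \code{ecdf}); default is estimated genome-wide from
#'   \code{frags}.
#' @return data.frame per pair: \code{peakA, peakB, distance,
#'   local_median, observed, expected, mean_support_len, p_value, q_value,
#'   significant, flagged} (\code{flagged} marks observed > 0 with zero
#'   expectation, where the p-value is set to the smallest representable
#'   value).
#' @export
testCoaccessibility <- function(pairs, peaks, frags, padBp = 0L,
                                fdr = 0.05, lengthCdf = NULL) {
    peaks <- sort(peaks)
    if (is.null(lengthCdf)) lengthCdf <- ecdf(width(frags))
    chrs <- as.character(seqnames(frags))
    sOf <- split(seq_along(frags), chrs)
    n <- nrow(pairs)
    obs <- integer(n); lam <- numeric(n); mlen <- rep(NA_real_, n)
    for (k in seq_len(n)) {
        A <- peaks[pairs$iA[k]]; B <- peaks[pairs$iB[k]]
        idx <- sOf[[as.character(seqnames(A))]]
        if (is.null(idx)) next
        s <- start(frags)[idx]; e <- end(frags)[idx]
        anch <- s >= start(A) - padBp & s <= end(A) + padBp
        if (!any(anch)) next
        sa <- s[anch]; ea <- e[anch]
        span <- ea >= start(B) - padBp & ea <= end(B) + padBp
        obs[k] <- sum(span)
        if (obs[k]) mlen[k] <- mean(ea[span] - sa[span] + 1L)
        ## right end in B  <=>  length in (B.start-s-1+pad, B.end-s+1+pad]
        lam[k] <- sum(lengthCdf(end(B) + padBp - sa + 1) -
                      lengthCdf(start(B) - padBp - sa))
    }
    p <- ppois(obs - 1L, lam, lower.tail = FALSE)
    flagged <- lam == 0 & obs > 0
    p[flagged] <- .Machine$double.xmin
    p[lam == 0 & obs == 0] <- 1
    q <- p.adjust(p, method = "BH")
    data.frame(peakA = pairs$peakA, peakB = pairs$peakB,
               distance = pairs$distance,
               local_median = pairs$local_median, observed = obs,
               expected = lam, mean_support_len = mlen, p_value = p,
               q_value = q, significant = q <= fdr, flagged = flagged,
               row.names = NULL)
}

#' Co-accessibility pipeline
#'
#' Candidate pair enumeration plus the spanning-molecule Poisson test.
#'
#' @inheritParams testCoaccessibility
#' @inheritParams coaccessCandidatePairs
#' @return See \code{\link{testCoaccessibility}}.
#' @export
coaccessibility <- function(frags, peaks, windowBp = 1e5, padBp = 0L,
                            fdr = 0.05, lengthCdf = NULL) {
    pairs <- coaccessCandidatePairs(peaks, frags, windowBp)
    if (!nrow(pairs))
        return(testCoaccessibility(pairs, peaks, frags, padBp, fdr,
                                   lengthCdf))
    testCoaccessibility(pairs, peaks, frags, padBp, fdr, lengthCdf)
}
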