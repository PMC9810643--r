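## Structural variants from long-read evidence: per-read candidates from
## CIGAR I/D operations and split-alignment anchors, single-linkage
## clustering across cells, distinct-cell support calling, benchmarking
## and somatic filtering.

#' Extract per-read SV candidates
#'
#' CIGAR insertion (I) operations of at least \code{minSvLen} become INS
#' candidates at the insertion point; deletion (D) operations become DEL
#' candidates spanning the deleted interval; a split-alignment anchor on a
#' different chromosome becomes a TRA candidate with the primary alignment
#' end and the anchor position as breakpoints.
#'
#' @param frags \code{\link{ScFragments}} with \code{cigar} /
#'   \code{anchors} evidence.
#' @param minSvLen Minimum INS/DEL length (default 50).
#' @return data.frame \code{(type, chrom, pos, length, chrom2, pos2, cell,
#'   read_id)}; TRA has length 0.
#' @export
extractSvCandidates <- function(frags, minSvLen = 50L) {
    mc <- mcols(frags)
    out <- list()
    ic <- which(nzchar(mc$cigar))
    if (length(ic)) {
        ops <- GenomicAlignments::explodeCigarOps(mc$cigar[ic])
        lens <- GenomicAlignments::explodeCigarOpLengths(mc$cigar[ic])
        for (k in seq_along(ic)) {
            i <- ic[k]
            op <- ops[[k]]; ln <- lens[[k]]
            consume <- op %in% c("M", "D", "N", "=", "X")
            refOff <- cumsum(c(0L, ifelse(consume, ln, 0L)))[seq_along(op)]
            hit <- which(op %in% c("I", "D") & ln >= minSvLen)
            if (!length(hit)) next
            out[[length(out) + 1L]] <- data.frame(
                type = ifelse(op[hit] == "I", "INS", "DEL"),
                chrom = as.character(seqnames(frags))[i],
                pos = start(frags)[i] + refOff[hit],
                length = ln[hit], chrom2 = NA_character_,
                pos2 = NA_integer_, cell = mc$cell[i],
                read_id = mc$read_id[i])
        }
    }
    ia <- which(nzchar(mc$anchors))
    for (i in ia) {
        for (a in strsplit(mc$anchors[i], ";", fixed = TRUE)[[1L]]) {
            f <- strsplit(a, ":", fixed = TRUE)[[1L]]
            if (f[1L] == as.character(seqnames(frags))[i]) next
            out[[length(out) + 1L]] <- data.frame(
                type = "TRA", chrom = as.character(seqnames(frags))[i],
                pos = end(frags)[i], length = 0L, chrom2 = f[1L],
                pos2 = as.integer(f[2L]), cell = mc$cell[i],
                read_id = mc$read_id[i])
        }
    }
    if (!length(out))
        return(data.frame(type = character(), chrom = character(),
                          pos = integer(), length = integer(),
                          chrom2 = character(), pos2 = integer(),
                          cell = character(), read_id = character()))
    as.data.frame(data.table::rbindlist(out))
}

## union-find root lookup (clusters are small; no path compression needed)
.ufFind <- function(parent, i) {
    while (parent[i] != i) i <- parent[i]
    i
}

.svMatchOk <- function(type, len1, len2, pos2a, pos2b, posTol,
                       minSizeRatio) {
    if (type == "TRA") abs(pos2a - pos2b) <= posTol
    else pmin(len1, len2) / pmax(len1, len2) >= minSizeRatio
}

#' Cluster SV candidates across cells
#'
#' Single-linkage clustering within each SV type: two INS/DEL candidates
#' merge when their positions are within \code{posTol} and their size
#' ratio is at least \code{minSizeRatio}; two TRA candidates merge when
#' both breakpoints are within \code{posTol}. Cluster position and length
#' are member medians; support is the set of distinct contributing cells.
#' The result is invariant to the input order.
#'
#' @param evidence Candidates from \code{\link{extractSvCandidates}}.
#' @param posTol Breakpoint tolerance in bp (default 500).
#' @param minSizeRatio Minimum min/max length ratio (default 0.7).
#' @return data.frame \code{(type, chrom, pos, length, chrom2, pos2,
#'   n_cells, n_reads, cells)}, sorted by (type, chrom, pos).
#' @export
clusterSvCandidates <- function(evidence, posTol = 500L,
                                minSizeRatio = 0.7) {
    ev <- evidence[order(evidence$type, evidence$chrom, evidence$pos,
                         evidence$cell, evidence$read_id), ]
    res <- list()
    grpKey <- paste(ev$type, ev$chrom,
                    ifelse(is.na(ev$chrom2), "", ev$chrom2))
    for (d in split(ev, grpKey)) {
        n <- nrow(d)
        parent <- seq_len(n)
        for (i in seq_len(n)) {
            j <- i - 1L
            while (j >= 1L && d$pos[i] - d$pos[j] <= posTol) {
                if (.svMatchOk(d$type[1L], d$length[i], d$length[j],
                               d$pos2[i], d$pos2[j], posTol,
                               minSizeRatio)) {
                    ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
                    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
                }
                j <- j - 1L
            }
        }
        root <- vapply(seq_len(n), function(i) .ufFind(parent, i), 0L)
        for (members in split(seq_len(n), root)) {
            cl <- d[members, ]
            res[[length(res) + 1L]] <- data.frame(
                type = cl$type[1L], chrom = cl$chrom[1L],
                pos = as.integer(round(median(cl$pos))),
                length = as.integer(round(median(cl$length))),
                chrom2 = cl$chrom2[1L],
                pos2 = if (is.na(cl$chrom2[1L])) NA_integer_
                       else as.integer(round(median(cl$pos2))),
                n_cells = length(unique(cl$cell)),
                n_reads = nrow(cl),
                cells = paste(sort(unique(cl$cell)), collapse = ","))
        }
    }
    if (!length(res))
        return(data.frame(type = character(), chrom = character(),
                          pos = integer(), length = integer(),
                          chrom2 = character(), pos2 = integer(),
                          n_cells = integer(), n_reads = integer(),
                          cells = character()))
    out <- as.data.frame(data.table::rbindlist(res))
    out[order(out$type, out$chrom, out$pos), , drop = FALSE]
}

#' Call SVs supported by enough distinct cells
#'
#' @param clusters \code{\link{clusterSvCandidates}} output.
#' @param minCells Minimum distinct supporting cells (default 5).
#' @return Subset of clusters with \code{n_cells >= minCells}.
#' @export
callSvs <- function(clusters, minCells = 5L)
    clusters[clusters$n_cells >= minCells, , drop = FALSE]

## greedy one-to-one matching of called against truth, closest first
.svMatch <- function(called, truth, posTol, minSizeRatio) {
    cand <- list()
    for (i in seq_len(nrow(called))) for (j in seq_len(nrow(truth))) {
        if (called$type[i] != truth$type[j]) next
        if (called$chrom[i] != truth$chrom[j]) next
        dpos <- abs(called$pos[i] - truth$pos[j])
        if (dpos > posTol) next
        if (called$type[i] == "TRA") {
            if (is.na(called$chrom2[i]) || is.na(truth$chrom2[j]) ||
                called$chrom2[i] != truth$chrom2[j] ||
                abs(called$pos2[i] - truth$pos2[j]) > posTol) next
        } else {
            r <- min(called$length[i], truth$length[j]) /
                max(called$length[i], truth$length[j])
            if (r < minSizeRatio) next
        }
        cand[[length(cand) + 1L]] <- c(i, j, dpos)
    }
    if (!length(cand)) return(cbind(i = integer(), j = integer()))
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand[, 3L]), , drop = FALSE]
    usedC <- logical(nrow(called)); usedT <- logical(nrow(truth))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (!usedC[i] && !usedT[j]) {
            usedC[i] <- TRUE; usedT[j] <- TRUE; keep[k] <- TRUE
        }
    }
    cand[keep, 1:2, drop = FALSE]
}

#' Benchmark SV calls against a truth set
#'
#' Greedy one-to-one matching by breakpoint proximity under the clustering
#' match rule; precision = matched called / called, recall = matched truth
#' / truth, overall and per type.
#'
#' @param called,truth SV tables (same convention as
#'   \code{\link{clusterSvCandidates}}; truth needs \code{type, chrom,
#'   pos, length} and \code{chrom2, pos2} for TRA).
#' @param posTol Matching tolerance (default 1000).
#' @param minSizeRatio Minimum size ratio for INS/DEL matches.
#' @return data.frame with rows "all" plus each type:
#'   \code{(type, n_called, n_truth, n_matched, precision, recall)}.
#' @export
benchmarkSvs <- function(called, truth, posTol = 1000L,
                         minSizeRatio = 0.7) {
    if (!nrow(truth)) stop("empty SV truth set")
    m <- .svMatch(called, truth, posTol, minSizeRatio)
    types <- sort(unique(c(called$type, truth$type)))
    row <- function(label, ci, ti) {
        nm <- sum(m[, 1L] %in% ci)
        data.frame(type = label, n_called = length(ci),
                   n_truth = length(ti), n_matched = nm,
                   precision = if (length(ci)) nm / length(ci) else NaN,
                   recall = if (length(ti))
                       sum(m[, 2L] %in% ti) / length(ti) else NaN)
    }
    out <- rbind(row("all", seq_len(nrow(called)), seq_len(nrow(truth))),
                 do.call(rbind, lapply(types, function(tp)
                     row(tp, which(called$type == tp),
                         which(truth$type == tp)))))
    rownames(out) <- NULL
    out
}

#' Precision/recall sweep over the cell-support threshold
#'
#' @param clusters Clustered candidates (\code{\link{clusterSvCandidates}}).
#' @param truth Truth SV table.
#' @param minCellsRange Integer thresholds to sweep (default 1:10).
#' @param posTol,minSizeRatio Matching parameters.
#' @return data.frame \code{(min_cells, type, precision, recall, ...)}.
#' @export
svSupportSweep <- function(clusters, truth, minCellsRange = 1:10,
                           posTol = 1000L, minSizeRatio = 0.7) {
    out <- lapply(minCellsRange, function(k) {
        b <- benchmarkSvs(callSvs(clusters, k), truth, posTol,
                          minSizeRatio)
        cbind(min_cells = k, b)
    })
    do.call(rbind, out)
}

#' Filter somatic SVs against a control call set
#'
#' Case calls with no control match under the benchmark matching rule
#' (germline events, shared with the control, are removed).
#'
#' @param caseCalls,controlCalls SV call tables.
#' @param posTol,minSizeRatio Matching parameters (defaults 1000, 0.7).
#' @return Subset of \code{caseCalls}.
#' @export
somaticFilter <- function(caseCalls, controlCalls, posTol = 1000L,
                          minSizeRatio = 0.7) {
    if (!nrow(caseCalls) || !nrow(controlCalls)) return(caseCalls)
    matched <- rep(FALSE, nrow(caseCalls))
    for (i in seq_len(nrow(caseCalls))) {
        for (j in seq_len(nrow(controlCalls))) {
            if (caseCalls$type[i] != controlCalls$type[j]) next
            if (caseCalls$chrom[i] != controlCalls$chrom[j]) next
            if (abs(caseCalls$pos[i] - controlCalls$pos[j]) > posTol) next
            if (caseCalls$type[i] == "TRA") {
                if (!is.na(caseCalls$chrom2[i]) &&
                    !is.na(controlCalls$chrom2[j]) &&
                    caseCalls$chrom2[i] == controlCalls$chrom2[j] &&
                    abs(caseCalls$pos2[i] - controlCalls$pos2[j]) <=
                        posTol) { matched[i] <- TRUE; break }
            } else {
                r <- min(caseCalls$length[i], controlCalls$length[j]) /
                    max(caseCalls$length[i], controlCalls$length[j])
                if (r >= minSizeRatio) { matched[i] <- TRUE; break }
            }
        }
    }
    caseCalls[!matched, , drop = FALSE]
}
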