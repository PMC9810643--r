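## Allele-specific accessibility: haplotype long reads from phased het
## SNPs (inside or flanking the peak), test peaks for allelic imbalance
## with BH FDR control, phase unphased het SNPs from read co-coverage, and
## evaluate phasing by the switch error rate.

#' Haplotype reads from phased heterozygous SNPs
#'
#' Counts, per read, observed SNP alleles matching haplotype 1 vs
#' haplotype 2 and assigns the majority haplotype when the margin and
#' consistency rules hold; ties or thin evidence give "ambiguous". Reads
#' covering no phased het SNP are ambiguous, not an error. Because long
#' reads extend far beyond a peak, the informative SNPs may lie entirely
#' outside the peak of interest.
#'
#' @param obs Allele observations, data.frame
#'   \code{(read_id, chrom, pos, allele)} (see
#'   \code{\link{readAlleleObs}}).
#' @param variants Phased het SNPs (\code{\link{readVcfHets}}); unphased
#'   rows are ignored.
#' @param minSnps Minimum informative SNPs per read (default 1).
#' @param minMargin Minimum |n1 - n2| (default 1).
#' @param minConsistency Minimum max(n1, n2) / (n1 + n2) (default 0.67).
#' @return data.frame \code{(read_id, n_hap1, n_hap2, assigned)} with
#'   \code{assigned} in \code{hap1/hap2/ambiguous}, one row per read seen
#'   in \code{obs}.
#' @export
haplotypeReads <- function(obs, variants, minSnps = 1L, minMargin = 1L,
                           minConsistency = 0.67) {
    ph <- variants[variants$phased & !is.na(variants$hap1), ]
    dt <- data.table::as.data.table(obs)
    vt <- data.table::as.data.table(ph[, c("chrom", "pos", "hap1", "hap2")])
    m <- merge(dt, vt, by = c("chrom", "pos"))
    m[, `:=`(is1 = allele == hap1, is2 = allele == hap2)]
    cnt <- m[, .(n_hap1 = sum(is1), n_hap2 = sum(is2)), by = read_id]
    allReads <- unique(dt$read_id)
    out <- merge(data.table::data.table(read_id = allReads), cnt,
                 by = "read_id", all.x = TRUE)
    out[is.na(n_hap1), `:=`(n_hap1 = 0L, n_hap2 = 0L)]
    tot <- out$n_hap1 + out$n_hap2
    maj <- pmax(out$n_hap1, out$n_hap2)
    ok <- tot >= minSnps & abs(out$n_hap1 - out$n_hap2) >= minMargin &
        tot > 0 & maj / pmax(tot, 1L) >= minConsistency
    assigned <- rep("ambiguous", nrow(out))
    assigned[ok & out$n_hap1 > out$n_hap2] <- "hap1"
    assigned[ok & out$n_hap2 > out$n_hap1] <- "hap2"
    data.frame(read_id = out$read_id, n_hap1 = out$n_hap1,
               n_hap2 = out$n_hap2, assigned = assigned)
}

#' Per-peak haplotyped read counts
#'
#' A read supports a peak when one of its Tn5 insertion ends falls inside
#' it (the FRIP read-end convention); each haplotyped read counts at most
#' once per peak. Haplotype 1 is reported as maternal.
#'
#' @param ends Insertion ends (\code{\link{fragmentEnds}}).
#' @param peaks \code{GRanges} of peaks with a \code{name} column.
#' @param readHaps Output of \code{\link{haplotypeReads}} (or any
#'   data.frame with \code{read_id} and \code{assigned}).
#' @return data.frame \code{(peak, n_maternal, n_paternal)}, one row per
#'   peak.
#' @export
aspCounts <- function(ends, peaks, readHaps) {
    hap <- setNames(readHaps$assigned, readHaps$read_id)
    ov <- findOverlaps(ends, peaks)
    rid <- mcols(ends)$read_id[S4Vectors::queryHits(ov)]
    pk <- S4Vectors::subjectHits(ov)
    keep <- !duplicated(paste0(rid, "\r", pk))
    rid <- rid[keep]; pk <- pk[keep]
    h <- hap[rid]
    pn <- mcols(peaks)$name
    if (is.null(pn)) pn <- sprintf("peak%05d", seq_along(peaks))
    nm <- tabulate(pk[!is.na(h) & h == "hap1"], nbins = length(peaks))
    np <- tabulate(pk[!is.na(h) & h == "hap2"], nbins = length(peaks))
    data.frame(peak = pn, n_maternal = nm, n_paternal = np)
}

#' Call allele-specific peaks (ASPs)
#'
#' Two-sided exact binomial test of each peak's haplotyped read counts
#' against a 50:50 maternal:paternal null, Benjamini--Hochberg corrected
#' across all tested peaks; peaks with fewer than \code{minTotal}
#' haplotyped reads are not tested.
#'
#' @param counts data.frame \code{(peak, n_maternal, n_paternal)}
#'   (\code{\link{aspCounts}}).
#' @param minTotal Minimum haplotyped reads per tested peak (default 10).
#' @param fdr FDR level for calling direction (default 0.05).
#' @param nullProp Null maternal proportion (default 0.5; an empirical
#'   genome-wide ratio may be supplied instead).
#' @return data.frame \code{(peak, n_maternal, n_paternal, p_value,
#'   q_value, direction)} for tested peaks; \code{direction} is
#'   maternal/paternal iff \code{q_value <= fdr}, else "none".
#' @export
callAsp <- function(counts, minTotal = 10L, fdr = 0.05, nullProp = 0.5) {
    tot <- counts$n_maternal + counts$n_paternal
    tested <- counts[tot >= minTotal, , drop = FALSE]
    if (!nrow(tested)) {
        warning("no peak reaches minTotal haplotyped reads")
        return(data.frame(peak = character(), n_maternal = integer(),
                          n_paternal = integer(), p_value = numeric(),
                          q_value = numeric(), direction = character()))
    }
    p <- mapply(function(m, pp) binom.test(m, m + pp, nullProp)$p.value,
                tested$n_maternal, tested$n_paternal)
    q <- p.adjust(p, method = "BH")
    dirn <- ifelse(q > fdr, "none",
                   ifelse(tested$n_maternal > tested$n_paternal,
                          "maternal", "paternal"))
    data.frame(peak = tested$peak, n_maternal = tested$n_maternal,
               n_paternal = tested$n_paternal, p_value = p, q_value = q,
               direction = dirn, row.names = NULL)
}

#' Phase heterozygous SNPs from long reads
#'
#' Builds a graph over het SNPs with edge weight (#reads supporting cis) -
#' (#reads supporting trans) for every co-covered pair, drops zero-weight
#' (tied) edges, and phases each connected component by propagating along
#' its maximum-weight spanning tree: a positive edge keeps the neighbour in
#' cis (ref-with-ref), a negative one flips it. Components of a single SNP
#' remain unphased.
#'
#' @param obs Allele observations \code{(read_id, chrom, pos, allele)}.
#' @param variants Het SNPs (phased or not); only \code{chrom, pos, ref,
#'   alt} are used.
#' @return data.frame \code{(chrom, pos, ref, alt, hap1, hap2, phased,
#'   phase_set)}: within a phase block, \code{hap1} carries the alleles
#'   assigned to one haplotype (block orientation is arbitrary, as always
#'   for read-backed phasing).
#' @export
phaseVariants <- function(obs, variants) {
    v <- variants[order(variants$chrom, variants$pos), ]
    v$vid <- seq_len(nrow(v))
    dt <- data.table::as.data.table(obs)
    vt <- data.table::as.data.table(v[, c("chrom", "pos", "ref", "alt",
                                          "vid")])
    m <- merge(dt, vt, by = c("chrom", "pos"))
    m <- m[allele == ref | allele == alt]
    m[, bit := as.integer(allele == alt)]
    data.table::setkey(m, read_id)
    ## all co-covered SNP pairs within each read
    pairs <- m[, {
        if (.N < 2L) NULL else {
            o <- order(vid)
            i <- rep(seq_len(.N - 1L), rev(seq_len(.N - 1L)))
            j <- unlist(lapply(seq_len(.N - 1L),
                               function(k) seq.int(k + 1L, .N)))
            list(v1 = vid[o][i], v2 = vid[o][j],
                 cis = as.integer(bit[o][i] == bit[o][j]))
        }
    }, by = read_id]
    out <- v[, c("chrom", "pos", "ref", "alt")]
    out$hap1 <- NA_character_; out$hap2 <- NA_character_
    out$phased <- FALSE; out$phase_set <- "."
    if (!NROW(pairs)) return(out)
    ew <- pairs[, .(w = sum(cis) - sum(1L - cis)), by = .(v1, v2)]
    ew <- ew[w != 0L]
    if (!nrow(ew)) return(out)
    g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(ew$v1), to = as.character(ew$v2),
                   weight = abs(ew$w), sign = sign(ew$w)),
        directed = FALSE)
    mstg <- igraph::mst(g, weights = -igraph::E(g)$weight)
    comp <- igraph::components(mstg)
    vids <- as.integer(igraph::V(mstg)$name)
    phase <- rep(NA_integer_, nrow(v))
    for (ci in seq_len(comp$no)) {
        members <- which(comp$membership == ci)
        if (length(members) < 2L) next
        root <- members[1L]
        bfs <- igraph::bfs(mstg, root = root, unreachable = FALSE,
                           father = TRUE)
        ordv <- as.integer(bfs$order[!is.na(bfs$order)])
        ph <- integer(0)
        ph[root] <- 0L
        for (u in ordv[-1L]) {
            f <- as.integer(bfs$father[u])
            eid <- igraph::get_edge_ids(mstg, c(f, u))
            sgn <- igraph::E(mstg)$sign[eid]
            ph[u] <- if (sgn > 0L) ph[f] else 1L - ph[f]
        }
        blockId <- as.character(min(vids[members]))
        for (u in members) {
            vv <- vids[u]
            phase[vv] <- ph[u]
            out$phase_set[vv] <- blockId
        }
    }
    done <- !is.na(phase)
    out$phased[done] <- TRUE
    out$hap1[done] <- ifelse(phase[done] == 0L, out$ref[done],
                             out$alt[done])
    out$hap2[done] <- ifelse(phase[done] == 0L, out$alt[done],
                             out$ref[done])
    out
}

#' Switch error rate of a phasing
#'
#' Over consecutive pairs of het SNPs phased in both the called and the
#' truth set (and lying in one called phase block), the fraction whose
#' relative phase disagrees. Invariant to flipping whole blocks.
#' Chromosomes with fewer than 2 shared phased SNPs are skipped.
#'
#' @param called,truth data.frames with \code{chrom, pos, ref, alt, hap1,
#'   phased} (and \code{phase_set} for \code{called}).
#' @return List: \code{per_chrom} (data.frame of chrom, n_pairs,
#'   switch_rate) and \code{median} across chromosomes.
#' @export
switchErrorRate <- function(called, truth) {
    ct <- merge(called[called$phased,
                       c("chrom", "pos", "alt", "hap1", "phase_set")],
                truth[truth$phased, c("chrom", "pos", "hap1")],
                by = c("chrom", "pos"), suffixes = c("_c", "_t"))
    ct <- ct[order(ct$chrom, ct$pos), ]
    rows <- lapply(split(ct, ct$chrom), function(d) {
        if (nrow(d) < 2L) return(NULL)
        i <- seq_len(nrow(d) - 1L)
        same <- d$phase_set[i] == d$phase_set[i + 1L]
        if (!any(same)) return(NULL)
        bc <- as.integer(d$hap1_c == d$alt)
        bt <- as.integer(d$hap1_t == d$alt)
        relC <- xor(bc[i], bc[i + 1L])
        relT <- xor(bt[i], bt[i + 1L])
        mism <- relC[same] != relT[same]
        data.frame(chrom = d$chrom[1L], n_pairs = sum(same),
                   switch_rate = mean(mism))
    })
    per <- do.call(rbind, rows)
    list(per_chrom = per,
         median = if (is.null(per)) NaN else median(per$switch_rate))
}
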