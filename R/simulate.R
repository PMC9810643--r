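## Synthetic long-read scATAC experiments with planted ground truth.
##
## Generative model (see the methods vignette): each fragment anchors one
## Tn5 insertion (its left end) either in an accessible peak or uniformly in
## the background; the other end follows from a log-normal fragment-length
## law. Planted co-accessible molecules instead place one end in each peak
## of a pair. Haplotypes, SNP allele observations, SV evidence (CIGAR /
## split anchors), per-cell CNV sampling intensity and cross-species
## doublets are layered on top, and everything planted is recorded in a
## SimTruth ledger.

#' Simulate a long-read scATAC experiment
#'
#' @param cfg A \code{\link{simConfig}} object.
#' @return A list with elements \code{fragments}
#'   (\code{\link{ScFragments}}), \code{alleleObs} (per-read SNP allele
#'   observations, see \code{\link{readAlleleObs}}), \code{variants}
#'   (planted phased het SNPs) and \code{truth} (\linkS4class{SimTruth}).
#'   Output is byte-identical for a fixed \code{cfg@seed}.
#' @export
simulateExperiment <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    set.seed(cfg@seed)
    chroms <- names(cfg@chromLengths)
    clen <- cfg@chromLengths

    peaks <- .simPlacePeaks(cfg)
    pairTab <- metadata(peaks)$pairs

    nAsp <- round(cfg@fracAsp * length(peaks))
    isAsp <- rep(FALSE, length(peaks))
    if (nAsp > 0) isAsp[sample(length(peaks), nAsp)] <- TRUE
    mcols(peaks)$isAsp <- isAsp
    mcols(peaks)$aspSkew <- ifelse(isAsp, cfg@aspSkew, 0.5)
    mcols(peaks)$aspDirection <-
        ifelse(!isAsp, "none",
               ifelse(cfg@aspSkew >= 0.5, "maternal", "paternal"))

    variants <- .simVariants(cfg)

    cells <- sprintf("cell%04d", seq_len(cfg@nCells))
    cellSpecies <- rep(NA_character_, cfg@nCells)
    doublets <- character()
    if (cfg@speciesMixing) {
        cellSpecies <- rep(c("human", "mouse"), length.out = cfg@nCells)
        doublets <- cells[runif(cfg@nCells) < cfg@doubletFraction]
    }

    cnv <- .simCnvGroups(cfg, cells, peaks)

    frag <- .simFragments(cfg, cells, peaks, cnv, cellSpecies, doublets)
    extra <- .simCoaccessReads(cfg, cells, peaks, pairTab,
                               nBase = nrow(frag))
    if (!is.null(extra) && nrow(extra$reads)) {
        if (cfg@speciesMixing) {
            ci <- match(extra$reads$cell, cells)
            own <- cellSpecies[ci]
            isDbl <- extra$reads$cell %in% doublets
            flip <- ifelse(isDbl, 0.5, cfg@speciesNoise)
            other <- ifelse(own == "human", "mouse", "human")
            extra$reads$species <- ifelse(runif(nrow(extra$reads)) < flip,
                                          other, own)
        }
        frag <- rbind(frag, extra$reads)
    }

    frag <- .simApplySvs(cfg, frag, cells)
    svTruth <- frag$svTruth; frag <- frag$frag

    obs <- .simAlleleObs(cfg, frag, variants)

    gr <- GRanges(frag$chrom, IRanges(frag$start, frag$end),
                  cell = frag$cell, mapq = 60L, read_id = frag$read_id,
                  cigar = frag$cigar, anchors = frag$anchors,
                  species = frag$species)
    seqlengths(gr) <- clen[seqlevels(gr)]
    fragments <- ScFragments(sort(gr))

    truth <- new("SimTruth", peaks = peaks, variants = variants,
                 svEvents = svTruth,
                 cnvSegments = cnv$truth,
                 doubletCells = doublets,
                 readHaplotypes = data.frame(read_id = frag$read_id,
                                             hap = frag$hap),
                 coaccessPairs = if (is.null(extra)) data.frame()
                                 else extra$truth)
    list(fragments = fragments, alleleObs = obs, variants = variants,
         truth = truth)
}

## Place nPeaks peaks, the first 2*coaccessPairs of them as planted pairs
## with centre distances drawn from coaccessGapRange. Peaks sit in equal
## genome slots so they never overlap and keep generous spacing.
.simPlacePeaks <- function(cfg) {
    chroms <- names(cfg@chromLengths); clen <- cfg@chromLengths
    nPairs <- cfg@coaccessPairs
    w <- cfg@peakWidthBp
    if (cfg@nPeaks < 2L * nPairs)
        stop("nPeaks must be >= 2 * coaccessPairs")
    if (cfg@nPeaks == 0L) {
        gr <- GRanges()
        metadata(gr)$pairs <- data.frame()
        return(gr)
    }
    nSingle <- cfg@nPeaks - 2L * nPairs
    units <- c(rep("pair", nPairs), rep("single", nSingle))
    uChrom <- rep(chroms, length.out = length(units))[
        sample(length(units))]
    maxGap <- max(cfg@coaccessGapRange)
    res <- list(); pairs <- list(); pid <- 0L
    for (ch in chroms) {
        mine <- units[uChrom == ch]
        if (!length(mine)) next
        slot <- floor(clen[[ch]] / length(mine))
        need <- ifelse(mine == "pair", 2 * w + maxGap + 2, w + 2)
        if (any(slot < need))
            stop("infeasible config: chromosome ", ch,
                 " too short for its peaks")
        for (i in seq_along(mine)) {
            lo <- (i - 1L) * slot + 1L
            if (mine[i] == "single") {
                s <- lo + floor(runif(1, 0, slot - w))
                res[[length(res) + 1L]] <-
                    data.frame(chrom = ch, start = s, end = s + w - 1L,
                               pair = NA_integer_)
            } else {
                pid <- pid + 1L
                d <- round(runif(1, cfg@coaccessGapRange[1],
                                 cfg@coaccessGapRange[2]))
                d <- max(d, w + 1L)   # ensure non-overlap, d > 0
                s <- lo + floor(runif(1, 0, slot - w - d - 1))
                res[[length(res) + 1L]] <-
                    data.frame(chrom = ch, start = c(s, s + d),
                               end = c(s, s + d) + w - 1L, pair = pid)
                pairs[[pid]] <- data.frame(pair = pid, chrom = ch,
                                           distance = d)
            }
        }
    }
    df <- do.call(rbind, res)
    o <- order(match(df$chrom, chroms), df$start)
    df <- df[o, ]
    gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                  name = sprintf("peak%05d", seq_len(nrow(df))),
                  pair = df$pair)
    seqlengths(gr) <- clen[seqlevels(gr)]
    metadata(gr)$pairs <- if (length(pairs)) do.call(rbind, pairs)
                          else data.frame()
    gr
}

.simVariants <- function(cfg) {
    if (cfg@hetSnpPerBp <= 0)
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          hap1 = character(), hap2 = character(),
                          phased = logical(), phase_set = character()))
    out <- lapply(names(cfg@chromLengths), function(ch) {
        n <- floor(cfg@chromLengths[[ch]] * cfg@hetSnpPerBp)
        if (n == 0L) return(NULL)
        pos <- sort(sample.int(cfg@chromLengths[[ch]], n))
        ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
        alt <- vapply(ref, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        refIsH1 <- runif(n) < 0.5
        data.frame(chrom = ch, pos = pos, ref = ref, alt = unname(alt),
                   hap1 = ifelse(refIsH1, ref, alt),
                   hap2 = ifelse(refIsH1, alt, ref),
                   phased = TRUE, phase_set = ch)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## Per-cell CNV genotypes. Cells sharing the same set of carried segments
## form a group with one piecewise-constant sampling intensity (copy number
## over ploidy) and one per-peak weight vector.
.simCnvGroups <- function(cfg, cells, peaks) {
    n <- length(cells)
    pc <- cfg@plantedCnvs
    carried <- matrix(FALSE, nrow = n, ncol = nrow(pc))
    truthRows <- list()
    if (nrow(pc)) for (k in seq_len(nrow(pc))) {
        idx <- sample.int(n, round(pc$cellFraction[k] * n))
        carried[idx, k] <- TRUE
        truthRows[[k]] <- data.frame(pc[k, c("chrom", "start", "end", "cn")],
                                     cells = paste(cells[idx],
                                                   collapse = ","))
    }
    key <- apply(carried, 1L, function(z) paste(which(z), collapse = ","))
    genome <- GRanges(names(cfg@chromLengths),
                      IRanges(1L, cfg@chromLengths))
    groups <- lapply(split(seq_len(n), key), function(idx) {
        ks <- which(carried[idx[1L], ])
        seg <- genome; mcols(seg)$w <- cfg@ploidy
        if (length(ks)) {
            ev <- GRanges(pc$chrom[ks], IRanges(pc$start[ks], pc$end[ks]),
                          w = pc$cn[ks])
            rest <- GenomicRanges::setdiff(genome, ev)
            mcols(rest)$w <- cfg@ploidy
            seg <- sort(c(ev, rest))
        }
        pw <- rep(1, length(peaks))
        if (length(peaks)) {
            mid <- resize(granges(peaks), width = 1L, fix = "center")
            hit <- findOverlaps(mid, seg, select = "first")
            pw <- mcols(seg)$w[hit] / cfg@ploidy
            pw[is.na(pw)] <- 1
        }
        list(cells = idx, seg = seg, peakW = pw)
    })
    list(groups = groups,
         truth = if (length(truthRows)) do.call(rbind, truthRows)
                 else data.frame())
}

.simFragments <- function(cfg, cells, peaks, cnv, cellSpecies, doublets) {
    clen <- cfg@chromLengths
    groupOf <- integer(length(cells))
    for (g in seq_along(cnv$groups)) groupOf[cnv$groups[[g]]$cells] <- g
    isAsp <- if (length(peaks)) mcols(peaks)$isAsp else logical()
    out <- vector("list", length(cells))
    for (ci in seq_along(cells)) {
        n <- cfg@readsPerCell
        if (n == 0L) next
        grp <- cnv$groups[[groupOf[ci]]]
        L <- pmax(50, round(rlnorm(n, log(cfg@fragMedianBp), cfg@fragSigma)))
        inPeak <- length(peaks) > 0 & runif(n) < cfg@fracPeakReads
        chrom <- character(n); s <- integer(n); pk <- rep(NA_integer_, n)
        nb <- sum(!inPeak)
        if (nb) {
            wts <- mcols(grp$seg)$w * width(grp$seg)
            si <- sample.int(length(grp$seg), nb, replace = TRUE,
                             prob = wts)
            chrom[!inPeak] <- as.character(seqnames(grp$seg))[si]
            s[!inPeak] <- start(grp$seg)[si] +
                floor(runif(nb) * width(grp$seg)[si])
        }
        np <- sum(inPeak)
        if (np) {
            pi <- sample.int(length(peaks), np, replace = TRUE,
                             prob = grp$peakW)
            pk[inPeak] <- pi
            chrom[inPeak] <- as.character(seqnames(peaks))[pi]
            s[inPeak] <- start(peaks)[pi] +
                floor(runif(np) * width(peaks)[pi])
        }
        e <- pmin(s + L - 1L, clen[chrom])
        s <- pmax(s, 1L)
        bad <- e <= s          # anchored on the last base of a chromosome
        s[bad] <- pmax(1L, as.integer(clen[chrom[bad]]) - 1L)
        e[bad] <- s[bad] + 1L
        pM <- rep(0.5, n)
        aspRead <- !is.na(pk) & isAsp[ifelse(is.na(pk), 1L, pk)]
        pM[aspRead] <- cfg@aspSkew
        hap <- ifelse(runif(n) < pM, "hap1", "hap2")
        species <- rep(NA_character_, n)
        if (cfg@speciesMixing) {
            own <- cellSpecies[ci]
            other <- setdiff(c("human", "mouse"), own)
            if (cells[ci] %in% doublets)
                species <- sample(c(own, other), n, replace = TRUE)
            else
                species <- ifelse(runif(n) < cfg@speciesNoise, other, own)
        }
        out[[ci]] <- data.frame(
            chrom = chrom, start = s, end = e, cell = cells[ci],
            read_id = sprintf("%s_r%06d", cells[ci], seq_len(n)),
            hap = hap, cigar = "", anchors = "", species = species,
            stringsAsFactors = FALSE)
    }
    as.data.frame(data.table::rbindlist(out))
}

## Planted co-accessible molecules: for pair (A, B) the number of extra
## spanning reads is Poisson((enrichment - 1) * lambda0), lambda0 being the
## anchored-model expectation of left-in-A, right-in-B molecules, so the
## observed spanning count sits at ~enrichment times its null expectation.
.simCoaccessReads <- function(cfg, cells, peaks, pairTab, nBase) {
    if (!NROW(pairTab)) return(NULL)
    genomeLen <- sum(cfg@chromLengths)
    w <- cfg@peakWidthBp
    mu <- log(cfg@fragMedianBp); sg <- cfg@fragSigma
    rows <- list(); truth <- list()
    for (j in seq_len(nrow(pairTab))) {
        ab <- which(!is.na(mcols(peaks)$pair) &
                    mcols(peaks)$pair == pairTab$pair[j])
        A <- peaks[ab[1L]]; B <- peaks[ab[2L]]
        d <- start(B) - start(A)
        pLeftA <- (1 - cfg@fracPeakReads) * w / genomeLen +
            cfg@fracPeakReads / length(peaks)
        lmin <- d - w / 2; lmax <- d + w / 2 + w
        pLen <- plnorm(lmax, mu, sg) - plnorm(max(lmin, 1), mu, sg)
        lam0 <- nBase * pLeftA * pLen
        nx <- rpois(1L, max(cfg@coaccessEnrichment - 1, 0) * lam0)
        truth[[j]] <- data.frame(
            peakA = mcols(A)$name, peakB = mcols(B)$name, distance = d,
            lambda0 = lam0, extraReads = nx)
        if (nx == 0L) next
        sA <- start(A) + floor(runif(nx) * w)
        eB <- start(B) + floor(runif(nx) * w)
        who <- sample(cells, nx, replace = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
            chrom = as.character(seqnames(A)), start = sA, end = eB,
            cell = who,
            read_id = sprintf("coacc%03d_r%04d", j, seq_len(nx)),
            hap = sample(c("hap1", "hap2"), nx, replace = TRUE),
            cigar = "", anchors = "",
            species = NA_character_, stringsAsFactors = FALSE)
    }
    list(reads = as.data.frame(data.table::rbindlist(rows)),
         truth = do.call(rbind, truth))
}

.simApplySvs <- function(cfg, frag, cells) {
    sv <- cfg@plantedSvs
    if (!nrow(sv))
        return(list(frag = frag,
                    svTruth = data.frame(type = character(),
                                         chrom = character(),
                                         pos = integer(), length = integer(),
                                         chrom2 = character(),
                                         pos2 = integer(),
                                         cells = character())))
    truth <- sv
    truth$cells <- ""
    taken <- rep(FALSE, nrow(frag))
    for (k in seq_len(nrow(sv))) {
        carriers <- sample(cells, round(sv$cellFraction[k] * length(cells)))
        truth$cells[k] <- paste(sort(carriers), collapse = ",")
        type <- sv$type[k]; pos <- sv$pos[k]; len <- sv$length[k]
        inCell <- frag$cell %in% carriers & frag$chrom == sv$chrom[k] &
            !taken
        if (type == "DEL") {
            hit <- which(inCell & frag$start < pos &
                         frag$end > pos + len)
        } else {
            hit <- which(inCell & frag$start < pos & frag$end > pos)
        }
        if (!length(hit)) next
        taken[hit] <- TRUE
        jp <- round(rnorm(length(hit), 0, cfg@svPosJitterSd))
        jl <- pmax(ceiling(0.75 * len),
                   round(len * (1 + rnorm(length(hit), 0,
                                          cfg@svLenJitterRel))))
        if (type == "DEL") {
            x <- pmax(1L, pos + jp - frag$start[hit])
            y <- pmax(1L, frag$end[hit] - (frag$start[hit] + x + jl) + 1L)
            frag$cigar[hit] <- sprintf("%dM%dD%dM", x, jl, y)
        } else if (type == "INS") {
            x <- pmax(1L, pos + jp - frag$start[hit])
            y <- pmax(1L, frag$end[hit] - frag$start[hit] - x + 1L)
            frag$cigar[hit] <- sprintf("%dM%dI%dM", x, jl, y)
        } else if (type == "TRA") {
            newEnd <- pmax(frag$start[hit] + 1L, pos + jp)
            frag$end[hit] <- newEnd
            frag$anchors[hit] <- sprintf(
                "%s:%d:+", sv$chrom2[k],
                pmax(1L, sv$pos2[k] +
                     round(rnorm(length(hit), 0, cfg@svPosJitterSd))))
        } else stop("unknown planted SV type: ", type)
    }
    list(frag = frag, svTruth = truth[, c("type", "chrom", "pos", "length",
                                          "chrom2", "pos2", "cells")])
}

.simAlleleObs <- function(cfg, frag, variants) {
    if (!nrow(variants))
        return(data.frame(read_id = character(), chrom = character(),
                          pos = integer(), allele = character()))
    vg <- GRanges(variants$chrom, IRanges(variants$pos, width = 1L))
    fg <- GRanges(frag$chrom, IRanges(frag$start, frag$end))
    ov <- findOverlaps(vg, fg)
    vi <- S4Vectors::queryHits(ov); fi <- S4Vectors::subjectHits(ov)
    trueAllele <- ifelse(frag$hap[fi] == "hap1",
                         variants$hap1[vi], variants$hap2[vi])
    otherAllele <- ifelse(frag$hap[fi] == "hap1",
                          variants$hap2[vi], variants$hap1[vi])
    flip <- runif(length(vi)) < cfg@baseError
    data.frame(read_id = frag$read_id[fi], chrom = variants$chrom[vi],
               pos = variants$pos[vi],
               allele = ifelse(flip, otherAllele, trueAllele))
}

#' Downsample fragments from a pseudo-bulk pool
#'
#' Pools all input fragments and deals them into synthetic cells of exactly
#' \code{perCellReads} fragments each, sampled without replacement --- the
#' standard construction for throughput titrations (up to the platform's
#' ~10,000 reads/cell ceiling).
#'
#' @param frags \code{\link{ScFragments}} pool.
#' @param perCellReads Fragments per synthetic cell.
#' @param nCells Number of synthetic cells; default
#'   \code{floor(length(frags) / perCellReads)}.
#' @param seed RNG seed.
#' @return \code{ScFragments} with cells relabelled
#'   \code{ds0001, ds0002, ...}.
#' @export
downsamplePseudobulk <- function(frags, perCellReads,
                                 nCells = NULL, seed = 1L) {
    if (is.null(nCells)) nCells <- floor(length(frags) / perCellReads)
    need <- nCells * perCellReads
    if (need > length(frags))
        stop("pool too small: need ", need, " fragments, have ",
             length(frags))
    set.seed(seed)
    idx <- sample.int(length(frags), need)
    out <- frags[idx]
    mcols(out)$cell <- rep(sprintf("ds%04d", seq_len(nCells)),
                           each = perCellReads)
    sort(out)
}
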