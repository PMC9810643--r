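## One-command synthetic end-to-end demonstration: simulate a small
## experiment with every planted feature, run qc -> peaks -> asp -> phase
## -> sv -> cnv -> coaccess, and compare recovered against planted truth.

#' Run the synthetic end-to-end demo
#'
#' Simulates a 100-cell, two-chromosome experiment with planted peaks,
#' ASPs, het SNPs, SVs, CNV subclones, doublets and co-accessible pairs,
#' runs every analysis stage, writes all result tables plus a
#' \code{report.tsv} of recovery checks into \code{outdir}, and fails
#' (error) if any stage errors. Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param outdir Output directory; refuses to write into an existing
#'   non-empty directory unless \code{force = TRUE}.
#' @param force Overwrite an existing non-empty \code{outdir}.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the \code{report} data.frame (one row
#'   per recovery check) and \code{pass} (all checks passed).
#' @export
runDemo <- function(seed = 1L, outdir = tempfile("longatac_demo"),
                    force = FALSE, quiet = FALSE) {
    if (dir.exists(outdir) && length(dir(outdir)) && !force)
        stop("output directory ", outdir,
             " exists and is not empty (use force = TRUE)")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (!quiet) message("[demo] ", ...)

    cfg <- simConfig(
        nCells = 100L, chromLengths = c(chr1 = 5e6, chr2 = 5e6),
        nPeaks = 100L, peakWidthBp = 500L, fracAsp = 0.1, aspSkew = 0.9,
        readsPerCell = 800L, fracPeakReads = 0.5,
        hetSnpPerBp = 1 / 2000, baseError = 0.02,
        plantedSvs = data.frame(
            type = c("DEL", "DEL", "INS", "INS", "TRA"),
            chrom = c("chr1", "chr2", "chr1", "chr2", "chr1"),
            pos = c(1.2e6, 3.4e6, 2.2e6, 1.7e6, 4.2e6),
            length = c(300L, 450L, 322L, 200L, 0L),
            chrom2 = c(NA, NA, NA, NA, "chr2"),
            pos2 = c(NA, NA, NA, NA, 4.6e6),
            cellFraction = 0.6),
        plantedCnvs = data.frame(chrom = "chr2", start = 1L, end = 2e6,
                                 cn = 3, cellFraction = 0.25),
        speciesMixing = TRUE, doubletFraction = 0.02,
        coaccessPairs = 5L, coaccessGapRange = c(2000, 8000),
        coaccessEnrichment = 4, seed = seed)

    say("simulating (seed ", seed, ") ...")
    sim <- simulateExperiment(cfg)
    frags <- sim$fragments
    truth <- sim$truth
    writeFragments(frags, file.path(outdir, "fragments.tsv"))
    writeVcfHets(sim$variants, file.path(outdir, "hets.vcf"))

    checks <- list()
    addCheck <- function(name, value, pass)
        checks[[length(checks) + 1L]] <<-
            data.frame(check = name, value = round(value, 4), pass = pass)

    say("qc ...")
    ends <- fragmentEnds(frags)
    tss <- resize(granges(truthPeaks(truth)), width = 1L, fix = "center")
    strand(tss) <- "+"
    qc <- cellQc(frags, peaks = truthPeaks(truth), tss = tss)
    utils::write.table(qc, file.path(outdir, "cell_qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fripAll <- frip(ends, truthPeaks(truth))
    addCheck("frip_above_background", fripAll,
             fripAll > sum(width(truthPeaks(truth))) /
                 sum(cfg@chromLengths) * 2)
    db <- classifyDoublets(frags)
    planted <- truthDoublets(truth)
    fp <- sum(db$is_doublet & !(db$cell %in% planted))
    addCheck("doublets_recovered",
             if (length(planted))
                 mean(planted %in% db$cell[db$is_doublet]) else 1,
             (length(planted) == 0L ||
              all(planted %in% db$cell[db$is_doublet])) &&
             fp <= ceiling(0.01 * nrow(db)))

    say("peak calling ...")
    called <- callPeaks(ends)
    writePeakBed(called, file.path(outdir, "peaks.bed"))
    bm <- benchmarkPeaks(called, truthPeaks(truth))
    addCheck("peak_recall", bm$recall, bm$recall >= 0.9)
    addCheck("peak_precision", bm$precision, bm$precision >= 0.8)

    say("allele-specific peaks ...")
    haps <- haplotypeReads(sim$alleleObs, sim$variants)
    cnts <- aspCounts(ends, truthPeaks(truth), haps)
    asp <- callAsp(cnts)
    utils::write.table(asp, file.path(outdir, "asp.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    isAsp <- setNames(mcols(truthPeaks(truth))$isAsp,
                      mcols(truthPeaks(truth))$name)
    sig <- asp$peak[asp$direction != "none"]
    power <- if (any(isAsp)) mean(names(isAsp)[isAsp] %in% sig) else 1
    fdrReal <- if (length(sig)) mean(!isAsp[sig]) else 0
    addCheck("asp_power", power, power >= 0.8)
    addCheck("asp_fdr", fdrReal, fdrReal <= 0.1)

    say("phasing ...")
    phased <- phaseVariants(sim$alleleObs, sim$variants)
    utils::write.table(phased, file.path(outdir, "phased_snps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    se <- switchErrorRate(phased, sim$variants)
    addCheck("switch_error_median", se$median, se$median < 0.02)

    say("structural variants ...")
    cands <- extractSvCandidates(frags)
    clusters <- clusterSvCandidates(cands)
    calls <- callSvs(clusters, minCells = 5L)
    writeSvTable(calls, file.path(outdir, "sv.tsv"))
    svb <- benchmarkSvs(calls, truthSvs(truth))
    addCheck("sv_recall", svb$recall[svb$type == "all"],
             svb$recall[svb$type == "all"] >= 0.8)
    addCheck("sv_precision", svb$precision[svb$type == "all"],
             svb$precision[svb$type == "all"] >= 0.9)

    say("copy number ...")
    bc <- binCounts(frags, binBp = 1e6)
    norm <- normalizeCnv(bc, reference = "median")
    gainCells <- strsplit(truthCnvs(truth)$cells[1L], ",")[[1L]]
    agg <- aggregateCnv(norm, list(
        gain = gainCells,
        base = setdiff(rownames(norm$cn), gainCells)))
    utils::write.table(
        cbind(as.data.frame(norm$bins)[, 1:3], t(norm$depth)),
        file.path(outdir, "cnv_depth.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    gainBins <- overlapsAny(norm$bins,
                            GRanges(truthCnvs(truth)$chrom[1L],
                                    IRanges(truthCnvs(truth)$start[1L],
                                            truthCnvs(truth)$end[1L])))
    cnOk <- mean(agg$consensus["gain", gainBins] == 3)
    addCheck("cnv_gain_recovered", cnOk, cnOk >= 0.8)

    say("co-accessibility ...")
    co <- coaccessibility(frags, truthPeaks(truth))
    utils::write.table(co, file.path(outdir, "coaccess.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tp <- truthCoaccessPairs(truth)
    key <- paste(co$peakA, co$peakB)
    hit <- paste(tp$peakA, tp$peakB) %in% key[co$significant]
    coPower <- mean(hit)
    addCheck("coaccess_power", coPower, coPower >= 0.6)

    report <- do.call(rbind, checks)
    utils::write.table(report, file.path(outdir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("report written to ", file.path(outdir, "report.tsv"))
    if (!quiet) print(report)
    invisible(list(report = report, pass = all(report$pass)))
}
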