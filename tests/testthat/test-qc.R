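test_that("TSS score is ~1 on uniform ends and handles degenerate input", {
    set.seed(11)
    sl <- c(chr1 = 1e6)
    tss <- GRanges("chr1", IRanges(seq(100000, 900000, by = 40000),
                                   width = 1), strand = "+")
    ends <- mkEnds("chr1", sample.int(1e6, 50000, replace = TRUE),
                   seqlens = sl)
    r <- tssEnrichment(ends, tss)
    expect_equal(sum(r$profile), r$n_ends)     # conservation
    expect_lt(abs(r$score - 1), 0.35)
    ## all ends exactly at TSS -> empty outer flanks -> +Inf sentinel
    atTss <- mkEnds("chr1", rep(start(tss), 5L))
    expect_equal(tssEnrichment(atTss, tss)$score, Inf)
    ## no ends in flanks -> NaN with warning
    far <- mkEnds("chr1", rep(5000L, 10L))
    expect_warning(r0 <- tssEnrichment(far, tss[1]), "undefined")
    expect_true(is.nan(r0$score))
})

test_that("TSS score recovers a planted 5x centre enrichment", {
    set.seed(12)
    tss <- GRanges("chr1", IRanges(500000, width = 1), strand = "+")
    nBg <- 10000L
    bg <- mkEnds("chr1", sample(498000:502000, nBg, replace = TRUE))
    perBin <- nBg / 401
    ## the centre bin covers offsets [0, 9]
    extra <- mkEnds("chr1", sample(500000:500009, round(4 * perBin),
                                   replace = TRUE))
    r <- tssEnrichment(c(bg, extra), tss)
    expect_gt(r$score, 4); expect_lt(r$score, 6)
})

test_that("footprint profile is flat on uniform ends and dips centrally", {
    set.seed(13)
    sites <- GRanges("chr1", IRanges(seq(50000, 950000, by = 50000),
                                     width = 1))
    pos <- sample.int(1e6, 80000, replace = TRUE)
    prof <- footprintProfile(mkEnds("chr1", pos), sites,
                             flankBp = 1000L, binBp = 50L)
    expect_lt(max(prof) / min(prof), 2.5)
    ## planted protection: remove ends within +/- 50 bp of the centres
    keep <- !overlapsAny(mkEnds("chr1", pos),
                         suppressWarnings(resize(sites, 101,
                                                 fix = "center")))
    dip <- footprintProfile(mkEnds("chr1", pos[keep]), sites,
                            flankBp = 1000L, binBp = 50L)
    nb <- length(dip)
    centreIdx <- which.min(dip)
    expect_lte(abs(centreIdx - (nb %/% 2 + 1)), 1)
    expect_lt(min(dip), mean(dip[c(1:5, (nb - 4):nb)]) / 2)
    ## single site, single end at centre -> delta profile
    delta <- footprintProfile(mkEnds("chr1", 50000L), sites[1])
    expect_equal(sum(delta), 1L)
    expect_equal(unname(delta[length(delta) %/% 2 + 1]), 1L)
})

test_that("FRIP follows its definition and the mixture expectation", {
    peaks <- GRanges("chr1", IRanges(c(1000, 5000), width = 500))
    inPk <- mkEnds("chr1", sample(1000:1499, 80, replace = TRUE))
    outPk <- mkEnds("chr1", sample(20000:90000, 120, replace = TRUE))
    expect_equal(frip(c(inPk, outPk), peaks), 0.40)
    expect_equal(frip(inPk, GRanges("chr1", IRanges(1, 1e6))), 1.0)
    expect_true(is.nan(frip(inPk[0], peaks)))
    ## planted mixture: w in peaks, rest uniform; expectation w + (1-w)cov
    set.seed(14)
    sl <- c(chr1 = 1e6)
    pk2 <- GRanges("chr1", IRanges(seq(10000, 990000, by = 20000),
                                   width = 1000))
    w <- 0.3; n <- 50000
    fromPk <- sample(unlist(mapply(seq, start(pk2), end(pk2))),
                     round(w * n), replace = TRUE)
    bg <- sample.int(1e6, n - round(w * n), replace = TRUE)
    cov <- sum(width(pk2)) / 1e6
    expected <- w + (1 - w) * cov
    expect_lt(abs(frip(mkEnds("chr1", c(fromPk, bg), seqlens = sl), pk2) -
                  expected), 0.02)
    ## permutation invariance and monotonicity under union
    expect_equal(frip(c(inPk, outPk), rev(peaks)),
                 frip(c(inPk, outPk), peaks))
    bigger <- c(peaks, GRanges("chr1", IRanges(20000, 30000)))
    expect_gte(frip(c(inPk, outPk), bigger), frip(c(inPk, outPk), peaks))
})

test_that("doublet calls follow the minor-fraction rule monotonically", {
    fr <- mkFrags("chr1", 1:200 * 100L, 1:200 * 100L + 500L,
                  cell = rep(c("c1", "c2"), each = 100),
                  species = c(rep("human", 55), rep("mouse", 45),
                              rep("human", 98), rep("mouse", 2)))
    db <- classifyDoublets(fr, minMinorFraction = 0.1)
    expect_true(db$is_doublet[db$cell == "c1"])     # 0.55 / 0.45
    expect_false(db$is_doublet[db$cell == "c2"])    # 0.98 / 0.02
    ## raising the threshold never increases the doublet count
    counts <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.45),
                     function(th) sum(classifyDoublets(fr, th)$is_doublet),
                     0L)
    expect_true(all(diff(counts) <= 0))
})

test_that("planted doublets are recovered at the configured rate", {
    cfg <- simConfig(nCells = 500L, readsPerCell = 100L, nPeaks = 0L,
                     fracPeakReads = 0, speciesMixing = TRUE,
                     doubletFraction = 0.02, seed = 21L)
    sim <- simulateExperiment(cfg)
    db <- classifyDoublets(sim$fragments)
    called <- db$cell[db$is_doublet]
    expect_setequal(called, truthDoublets(sim$truth))
    ## recovered rate within the binomial 95% CI of the planted rate
    ci <- qbinom(c(0.025, 0.975), 500, 0.02)
    expect_gte(length(called), ci[1])
    expect_lte(length(called), ci[2])
})
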