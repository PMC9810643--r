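test_that("a dense window is called and sparse input is not", {
    set.seed(31)
    sl <- c(chr1 = 1e6)
    ## uniform background at lambda ~ 1 per 500-bp window
    bg <- mkEnds("chr1", sample.int(1e6, 2000, replace = TRUE),
                 seqlens = sl)
    ## k = 20 ends in one window: Poisson tail ~3.5e-19 << 1e-5
    hot <- mkEnds("chr1", sample(500000:500099, 20, replace = TRUE),
                  seqlens = sl)
    pk <- callPeaks(c(bg, hot))
    expect_true(any(overlapsAny(GRanges("chr1", IRanges(500000, 500100)),
                                pk)))
    ## closed-form oracle for that window
    expect_lt(ppois(19, 1, lower.tail = FALSE), 1e-5)
    ## below min_ends nothing can be called
    few <- mkEnds("chr1", c(1000L, 2000L, 3000L), seqlens = sl)
    expect_equal(length(callPeaks(few)), 0L)
    expect_equal(length(callPeaks(few[0])), 0L)
})

test_that("nearby significant windows merge into one peak", {
    sl <- c(chr1 = 1e6)
    c1 <- mkEnds("chr1", rep(10000:10009, 3), seqlens = sl)
    c2 <- mkEnds("chr1", rep(10600:10609, 3), seqlens = sl)
    bg <- mkEnds("chr1", seq(1, 1e6, by = 1000), seqlens = sl)
    pk <- callPeaks(c(c1, c2, bg))
    hits <- subsetByOverlaps(pk, GRanges("chr1", IRanges(9000, 12000)))
    expect_equal(length(hits), 1L)         # merged across the 600-bp gap
    expect_true(all(start(pk) <= end(pk)))
    expect_equal(pk, sort(pk))             # sorted, disjoint output
    expect_true(all(width(reduce(pk)) == width(pk)))
})

test_that("relaxing the p threshold never loses called regions", {
    set.seed(32)
    sim <- simulateExperiment(simConfig(nCells = 10L, readsPerCell = 500L,
                                        nPeaks = 30L, seed = 8L))
    ends <- fragmentEnds(sim$fragments)
    strict <- callPeaks(ends, peakCallParams(pThreshold = 1e-8))
    loose <- callPeaks(ends, peakCallParams(pThreshold = 1e-4))
    expect_true(all(overlapsAny(strict, loose)))
})

test_that("the caller recovers planted peaks from a deep pool", {
    sim <- simulateExperiment(simConfig(nCells = 50L, readsPerCell = 600L,
                                        nPeaks = 100L, seed = 9L))
    pk <- callPeaks(fragmentEnds(sim$fragments))
    bm <- benchmarkPeaks(pk, truthPeaks(sim$truth))
    expect_gte(bm$recall, 0.9)
    expect_gte(bm$precision, 0.8)
})

test_that("peak overlap counts are asymmetric and match printed ratios", {
    a <- GRanges("chr1", IRanges(c(1, 100), width = 10))
    b <- GRanges("chr1", IRanges(5, 15))
    ov <- peakOverlap(a, b)
    expect_equal(ov$n_overlap_a, 1L); expect_equal(ov$frac_a, 0.5)
    expect_equal(ov$n_overlap_b, 1L); expect_equal(ov$frac_b, 1.0)
    one <- peakOverlap(GRanges("chr1", IRanges(1, 10)),
                       GRanges("chr1", IRanges(6, 15)))
    expect_equal(unlist(one), c(n_overlap_a = 1, frac_a = 1,
                                n_overlap_b = 1, frac_b = 1))
    disj <- peakOverlap(GRanges("chr1", IRanges(1, 10)),
                        GRanges("chr1", IRanges(100, 110)))
    expect_equal(unname(unlist(disj)), c(0, 0, 0, 0))
    ## reporting helper reproduces a printed percentage from its counts
    expect_equal(percentOf(27290, 49688), 54.9)
})

test_that("peak benchmarking enumerates matches both ways", {
    A <- GRanges("chr1", IRanges(100, 200))
    B <- GRanges("chr1", IRanges(1000, 1100))
    C <- GRanges("chr1", IRanges(5000, 5100))
    D <- GRanges("chr1", IRanges(9000, 9100))
    expect_equal(benchmarkPeaks(c(A, B), c(A, B)),
                 list(precision = 1.0, recall = 1.0))
    bm <- benchmarkPeaks(c(A, B, C), c(A, B, D))
    expect_equal(bm$precision, 2 / 3)
    expect_equal(bm$recall, 2 / 3)
    expect_error(benchmarkPeaks(A, GRanges()), "empty reference")
})

test_that("annotation assigns by priority and fractions sum to one", {
    ref <- GRanges("chr1", IRanges(c(100, 100, 5000), width = 300),
                   category = c("PLS", "dELS", "CTCF-only"))
    pks <- GRanges("chr1", IRanges(c(150, 5100, 90000), width = 50))
    ann <- annotatePeaks(pks, ref)
    expect_equal(sum(ann$fraction), 1)
    get <- function(cat) ann$n[ann$category == cat]
    expect_equal(get("PLS"), 1L)          # two categories, PLS wins
    expect_equal(get("CTCF-only"), 1L)
    expect_equal(get("unannotated"), 1L)
    ## single-category saturation
    ann2 <- annotatePeaks(pks[1], ref[1])
    expect_equal(ann2$fraction[ann2$category == "PLS"], 1)
})

test_that("peak and gene count matrices conserve end counts", {
    fr <- mkFrags("chr1", c(1000L, 3000L), c(1300L, 3400L),
                  cell = c("c1", "c2"))
    pks <- GRanges("chr1", IRanges(c(1000, 3000), width = 200),
                   name = c("p1", "p2"))
    m <- peakCellMatrix(fr, pks, 0L, 0L)
    expect_equal(dim(m), c(2L, 2L))
    expect_equal(as.numeric(m["c1", "p1"]), 1)
    expect_equal(as.numeric(m["c2", "p2"]), 1)
    ## column sums equal per-peak end counts (the FRIP numerator)
    ends <- fragmentEnds(fr, 0L, 0L)
    expect_equal(unname(Matrix::colSums(m)),
                 countOverlaps(pks, ends))
    ## gene scores include the strand-aware upstream window
    genes <- GRanges("chr1", IRanges(3350, 4000), strand = "-",
                     name = "g1")
    g <- geneScore(fr, genes, upstreamBp = 0L, 0L, 0L)
    expect_equal(as.numeric(g["c2", "g1"]), 1)   # right end at 3400
    g2 <- geneScore(fr, GRanges("chr1", IRanges(1400, 2000),
                                strand = "+", name = "g2"),
                    upstreamBp = 2000L, 0L, 0L)
    expect_equal(as.numeric(g2["c1", "g2"]), 2)  # both ends upstream
})

test_that("cell types separate in the peak matrix by counting alone", {
    set.seed(33)
    pks <- GRanges("chr1", IRanges(c(10000, 50000), width = 500),
                   name = c("typeA_peak", "typeB_peak"))
    sA <- sample(start(pks[1]):end(pks[1]), 200, replace = TRUE)
    sB <- sample(start(pks[2]):end(pks[2]), 200, replace = TRUE)
    fr <- mkFrags("chr1", c(sA, sB), c(sA, sB) + 4000L,
                  cell = c(sample(sprintf("A%02d", 1:10), 200, TRUE),
                           sample(sprintf("B%02d", 1:10), 200, TRUE)))
    m <- peakCellMatrix(fr, pks)
    isA <- startsWith(rownames(m), "A")
    expect_gt(mean(m[isA, "typeA_peak"]), mean(m[!isA, "typeA_peak"]) + 5)
    expect_gt(mean(m[!isA, "typeB_peak"]), mean(m[isA, "typeB_peak"]) + 5)
})
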