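test_that("read haplotyping follows majority, margin and tie rules", {
    v <- mkVariants("chr1", c(100L, 200L, 300L, 400L), ref = "A",
                    alt = "G", hap1 = "A")
    obs <- data.frame(
        read_id = c(rep("r1", 3), rep("r2", 4), rep("r3", 4), "r4", "r5",
                    "r5", "r5"),
        chrom = "chr1",
        pos = c(100, 200, 300,  100, 200, 300, 400,
                100, 200, 300, 400,  999,  100, 200, 300),
        allele = c("A", "A", "A",          # unanimous hap1
                   "A", "A", "G", "G",     # 2 vs 2 tie
                   "G", "G", "G", "A",     # 3 vs 1 majority hap2
                   "A",                    # covers no known het SNP
                   "G", "G", "A"))         # 2/3 < 0.67 consistency
    h <- haplotypeReads(obs, v)
    got <- setNames(h$assigned, h$read_id)
    expect_equal(got[["r1"]], "hap1")
    expect_equal(got[["r2"]], "ambiguous")
    expect_equal(got[["r3"]], "hap2")      # consistency 0.75 >= 0.67
    expect_equal(got[["r4"]], "ambiguous")
    expect_equal(got[["r5"]], "ambiguous")
    ## stricter consistency demotes the 3/4 read too
    h2 <- haplotypeReads(obs, v, minConsistency = 0.8)
    expect_equal(setNames(h2$assigned, h2$read_id)[["r3"]], "ambiguous")
})

test_that("haplotyping is accurate on simulated reads with base errors", {
    cfg <- simConfig(nCells = 10L, readsPerCell = 300L, nPeaks = 0L,
                     fracPeakReads = 0, hetSnpPerBp = 1 / 1200,
                     baseError = 0.05, seed = 41L)
    sim <- simulateExperiment(cfg)
    h <- haplotypeReads(sim$alleleObs, sim$variants, minSnps = 3L)
    th <- truthReadHaplotypes(sim$truth)
    assigned <- h[h$assigned != "ambiguous", ]
    acc <- mean(assigned$assigned ==
                th$hap[match(assigned$read_id, th$read_id)])
    expect_gte(acc, 0.95)
})

test_that("ASP p-values match the exact binomial and respect minTotal", {
    counts <- data.frame(peak = c("pk1", "pk2", "pk3"),
                         n_maternal = c(10L, 7L, 3L),
                         n_paternal = c(0L, 7L, 2L))
    r <- callAsp(counts, minTotal = 10L, fdr = 0.05)
    expect_equal(nrow(r), 2L)                        # pk3 under minTotal
    expect_equal(r$p_value[r$peak == "pk1"], 2 * 0.5^10)
    expect_equal(r$p_value[r$peak == "pk2"], 1.0)    # symmetric null
    expect_equal(r$direction[r$peak == "pk2"], "none")
    expect_equal(r$direction[r$peak == "pk1"], "maternal")
    expect_warning(callAsp(counts[3, , drop = FALSE]), "minTotal")
})

test_that("swapping haplotype labels swaps ASP directions only", {
    cfg <- simConfig(nCells = 20L, readsPerCell = 400L, nPeaks = 50L,
                     fracAsp = 0.1, aspSkew = 0.9,
                     hetSnpPerBp = 1 / 2000, seed = 42L)
    sim <- simulateExperiment(cfg)
    ends <- fragmentEnds(sim$fragments)
    v <- sim$variants
    vSwap <- v; vSwap$hap1 <- v$hap2; vSwap$hap2 <- v$hap1
    r1 <- callAsp(aspCounts(ends, truthPeaks(sim$truth),
                            haplotypeReads(sim$alleleObs, v)))
    r2 <- callAsp(aspCounts(ends, truthPeaks(sim$truth),
                            haplotypeReads(sim$alleleObs, vSwap)))
    expect_equal(r1$p_value, r2$p_value)
    expect_equal(r1$n_maternal, r2$n_paternal)
    swap <- c(maternal = "paternal", paternal = "maternal", none = "none")
    expect_equal(unname(swap[r1$direction]), r2$direction)
})

test_that("balanced peaks stay near the nominal false-call rate", {
    cfg <- simConfig(nCells = 25L, readsPerCell = 1200L, nPeaks = 500L,
                     chromLengths = c(chr1 = 3e6, chr2 = 3e6),
                     fracAsp = 0, hetSnpPerBp = 1 / 1500, seed = 43L)
    sim <- simulateExperiment(cfg)
    h <- haplotypeReads(sim$alleleObs, sim$variants)
    r <- callAsp(aspCounts(fragmentEnds(sim$fragments),
                           truthPeaks(sim$truth), h), fdr = 0.05)
    expect_lte(mean(r$direction != "none"), 0.05 * 1.5)
})

test_that("variant phasing handles unanimous, tied and flipped cases", {
    v <- mkVariants("chr1", c(1000L, 2000L), ref = "A", alt = "G")
    cis <- data.frame(read_id = rep(sprintf("r%d", 1:5), each = 2),
                      chrom = "chr1", pos = rep(c(1000, 2000), 5),
                      allele = rep(c("A", "A", "G", "G"), length.out = 10))
    ph <- phaseVariants(cis, v)
    expect_true(all(ph$phased))
    expect_equal(ph$phase_set[1], ph$phase_set[2])
    expect_equal(ph$hap1[1] == "A", ph$hap1[2] == "A")  # cis
    ## 3 cis vs 3 trans reads: zero-weight edge, no joint block
    tie <- data.frame(read_id = rep(sprintf("t%d", 1:6), each = 2),
                      chrom = "chr1", pos = rep(c(1000, 2000), 6),
                      allele = c(rep(c("A", "A"), 3), rep(c("A", "G"), 3)))
    pht <- phaseVariants(tie, v)
    expect_false(any(pht$phased))
})

test_that("switch error counts adjacent disagreements, flip-invariantly", {
    truth <- mkVariants("chr1", (1:5) * 1000L, ref = "A", alt = "G",
                        hap1 = "A")
    called <- truth
    expect_equal(switchErrorRate(called, truth)$median, 0)
    ## one internal flip at SNP 3 breaks both adjacent pairs: 2/4
    called2 <- truth
    called2$hap1[3] <- "G"; called2$hap2[3] <- "A"
    expect_equal(switchErrorRate(called2, truth)$median, 0.5)
    ## inverting the whole block changes nothing
    flipped <- truth
    flipped$hap1 <- truth$hap2; flipped$hap2 <- truth$hap1
    expect_equal(switchErrorRate(flipped, truth)$median, 0)
    ## pairs across different called blocks are not comparable
    twoBlocks <- truth
    twoBlocks$phase_set <- c("a", "a", "a", "b", "b")
    se <- switchErrorRate(twoBlocks, truth)
    expect_equal(se$per_chrom$n_pairs, 3L)
})

test_that("read-backed phasing recovers truth at low switch error", {
    cfg <- simConfig(nCells = 10L, chromLengths = c(chr1 = 2e5),
                     readsPerCell = 100L, nPeaks = 0L, fracPeakReads = 0,
                     hetSnpPerBp = 1 / 2000, baseError = 0.05, seed = 44L)
    sim <- simulateExperiment(cfg)
    ph <- phaseVariants(sim$alleleObs, sim$variants)
    expect_gte(mean(ph$phased), 0.9)
    se <- switchErrorRate(ph, sim$variants)
    expect_lt(se$median, 0.02)
})
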