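test_that("CIGAR walking places INS/DEL candidates and applies minSvLen", {
    ## 0-based start 10000 with 2000M322I1800M -> INS at 0-based 12000
    fr <- mkFrags("chr1", 10001L, 13800L, cigar = "2000M322I1800M")
    sv <- extractSvCandidates(fr)
    expect_equal(sv$type, "INS")
    expect_equal(sv$pos - 1L, 12000L)
    expect_equal(sv$length, 322L)
    ## short D op under threshold yields nothing
    fr2 <- mkFrags("chr1", 1001L, 3030L, cigar = "1000M30D1000M")
    expect_equal(nrow(extractSvCandidates(fr2, minSvLen = 50L)), 0L)
    ## D consumes reference: candidate spans the deleted interval
    fr3 <- mkFrags("chr1", 1001L, 3300L, cigar = "1000M300D1000M")
    sv3 <- extractSvCandidates(fr3)
    expect_equal(sv3$type, "DEL")
    expect_equal(sv3$pos, 2001L)
    expect_equal(sv3$length, 300L)
    ## split anchor on another chromosome is a translocation
    fr4 <- mkFrags("chr22", 23180001L, 23185000L,
                   anchors = "chr9:130714000:+")
    sv4 <- extractSvCandidates(fr4)
    expect_equal(sv4$type, "TRA")
    expect_equal(sv4$chrom2, "chr9")
    expect_equal(sv4$pos, 23185000L)   # primary alignment end
    expect_equal(sv4$pos2, 130714000L)
})

test_that("clustering merges by position and size ratio, single-linkage", {
    ev <- data.frame(type = "DEL", chrom = "chr1",
                     pos = c(1000L, 1100L), length = c(300L, 320L),
                     chrom2 = NA_character_, pos2 = NA_integer_,
                     cell = c("cellA", "cellB"),
                     read_id = c("r1", "r2"))
    cl <- clusterSvCandidates(ev)
    expect_equal(nrow(cl), 1L)
    expect_equal(cl$n_cells, 2L)           # ratio 300/320 = 0.94
    expect_equal(cl$pos, 1050L)
    ## incompatible sizes stay apart
    ev2 <- ev; ev2$length <- c(300L, 100L)
    expect_equal(nrow(clusterSvCandidates(ev2)), 2L)
    ## chain A-B-C merges even when A and C exceed the tolerance
    ev3 <- data.frame(type = "INS", chrom = "chr1",
                      pos = c(1000L, 1400L, 1800L), length = 200L,
                      chrom2 = NA_character_, pos2 = NA_integer_,
                      cell = c("c1", "c2", "c3"),
                      read_id = c("r1", "r2", "r3"))
    cl3 <- clusterSvCandidates(ev3, posTol = 500L)
    expect_equal(nrow(cl3), 1L)
    expect_equal(cl3$n_cells, 3L)
    ## order invariance
    shuf <- ev3[c(3, 1, 2), ]
    expect_identical(clusterSvCandidates(shuf, posTol = 500L), cl3)
})

test_that("calling requires distinct supporting cells", {
    oneCell <- data.frame(type = "DEL", chrom = "chr1", pos = 1000L,
                          length = 300L, chrom2 = NA_character_,
                          pos2 = NA_integer_, cell = "c1",
                          read_id = sprintf("r%d", 1:10))
    cl <- clusterSvCandidates(oneCell)
    expect_equal(cl$n_reads, 10L)
    expect_equal(cl$n_cells, 1L)
    expect_equal(nrow(callSvs(cl, minCells = 5L)), 0L)
    expect_equal(callSvs(cl, minCells = 1L), cl)
    fiveCells <- oneCell; fiveCells$cell <- sprintf("c%d", c(1:5, 1:5))
    expect_equal(nrow(callSvs(clusterSvCandidates(fiveCells), 5L)), 1L)
})

test_that("benchmark matching is one-to-one and exact on toy sets", {
    mkSet <- function(pos, type = "DEL")
        data.frame(type = type, chrom = "chr1", pos = pos, length = 300L,
                   chrom2 = NA_character_, pos2 = NA_integer_)
    tr <- mkSet(c(10000L, 50000L, 90000L))
    expect_equal(benchmarkSvs(tr, tr)$precision, rep(1, 2))
    ## called {A,B,X} vs truth {A,B,Y}
    called <- mkSet(c(10000L, 50000L, 200000L))
    b <- benchmarkSvs(called, tr)
    expect_equal(b$precision[b$type == "all"], 2 / 3)
    expect_equal(b$recall[b$type == "all"], 2 / 3)
    expect_error(benchmarkSvs(called, tr[0, ]), "empty")
})

test_that("somatic filtering removes shared events only", {
    mkSet <- function(pos)
        data.frame(type = "DEL", chrom = "chr1", pos = pos,
                   length = 300L, chrom2 = NA_character_,
                   pos2 = NA_integer_)
    case <- mkSet(c(10000L, 50000L, 90000L))
    ctrl <- mkSet(c(10050L, 50200L))
    som <- somaticFilter(case, ctrl)
    expect_equal(som$pos, 90000L)
    expect_equal(nrow(somaticFilter(case, case)), 0L)
})

test_that("planted somatic and germline SVs separate exactly", {
    shared <- data.frame(type = "DEL", chrom = "chr1",
                         pos = c(1e5, 3e5), length = c(200L, 400L),
                         chrom2 = NA, pos2 = NA, cellFraction = 1.0)
    caseOnly <- data.frame(type = "INS", chrom = "chr1", pos = 7e5,
                           length = 250L, chrom2 = NA, pos2 = NA,
                           cellFraction = 1.0)
    base <- simConfig(nCells = 20L, chromLengths = c(chr1 = 1e6),
                      readsPerCell = 1500L, nPeaks = 0L,
                      fracPeakReads = 0, seed = 51L,
                      plantedSvs = rbind(shared, caseOnly))
    ctrlCfg <- simConfig(nCells = 20L, chromLengths = c(chr1 = 1e6),
                         readsPerCell = 1500L, nPeaks = 0L,
                         fracPeakReads = 0, seed = 52L,
                         plantedSvs = shared)
    caseCalls <- callSvs(clusterSvCandidates(extractSvCandidates(
        simulateExperiment(base)$fragments)), 5L)
    ctrlCalls <- callSvs(clusterSvCandidates(extractSvCandidates(
        simulateExperiment(ctrlCfg)$fragments)), 5L)
    som <- somaticFilter(caseCalls, ctrlCalls)
    expect_equal(som$type, "INS")
    expect_lt(abs(som$pos - 7e5), 500)
})
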