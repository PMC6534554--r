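notI <- builtinEnzymes()$NotI

test_that("planted genomes contain exactly the requested motif occurrences", {
    sim <- simulateGenome(c(chr1 = 100000L),
                          embed = list(list(enzyme = notI, n = 10L)),
                          seed = 1L)
    expect_length(findCutSites(sim$genome, notI), 10L)
    expect_length(sim$sites, 10L)

    none <- simulateGenome(c(chr1 = 50000L), embed = list(), seed = 1L)
    expect_length(findCutSites(none$genome, notI), 0L)
})

test_that("generators are seed-deterministic", {
    a <- simulateGenome(c(chr1 = 60000L),
                        embed = list(list(enzyme = notI, n = 3L)), seed = 7L)
    b <- simulateGenome(c(chr1 = 60000L),
                        embed = list(list(enzyme = notI, n = 3L)), seed = 7L)
    expect_identical(as.character(a$genome), as.character(b$genome))

    g1 <- simulateGdna(a$genome, a$sites, fCut = 0.4, coverage = 100,
                       seed = 3L)
    g2 <- simulateGdna(a$genome, a$sites, fCut = 0.4, coverage = 100,
                       seed = 3L)
    expect_identical(g1$fragments, g2$fragments)

    r1 <- simulateDsbReads(a$genome, a$sites, 0.4, alpha = 200, seed = 5L)
    r2 <- simulateDsbReads(a$genome, a$sites, 0.4, alpha = 200, seed = 5L)
    expect_identical(r1$reads, r2$reads)

    u1 <- simulateUmiReads(a$sites, 0.1, 1000, seed = 9L)
    u2 <- simulateUmiReads(a$sites, 0.1, 1000, seed = 9L)
    expect_identical(u1$umis, u2$umis)
})

test_that("gDNA simulation respects the planted cutting probability edge cases", {
    sim <- fixtureGenome()
    ## fCut = 1: no fragment spans any site vicinity
    gd1 <- simulateGdna(sim$genome, sim$sites, fCut = 1, coverage = 200,
                        sonicationRate = 0, seed = 11L)
    cnt1 <- countsAtSites(gd1$fragments, sim$sites)
    expect_true(all(cnt1$nUncut == 0L))
    expect_true(all(cnt1$nCut > 0L))

    ## fCut = 0: cut-classified fragments only at the background end rate
    gd0 <- simulateGdna(sim$genome, sim$sites, fCut = 0, coverage = 200,
                        sonicationRate = 0, seed = 12L)
    cnt0 <- countsAtSites(gd0$fragments, sim$sites)
    ## end-in-vicinity rate for locally uniform coverage is ~(4w+2)/fragMean
    expect_lt(sum(cnt0$nCut), 0.1 * sum(cnt0$nCut + cnt0$nUncut))
    expect_true(all(cnt0$nUncut > 0L))
})

test_that("gDNA fragment ends abut the cut within 1 bp jitter", {
    sim <- fixtureGenome()
    gd <- simulateGdna(sim$genome, sim$sites, fCut = 0.6, coverage = 300,
                       sonicationRate = 0, seed = 13L)
    c0 <- cutPos0(sim$sites[1])
    ch <- as.character(seqnames(sim$sites[1]))
    fr <- gd$fragments[as.character(seqnames(gd$fragments)) == ch]
    ends <- c(start(fr) - 1L, end(fr))
    ## cleaved-molecule ends pile up within 1 bp of the cut; ends 2-3 bp
    ## away arise only from chance coverage boundaries and stay rare
    atCut <- sum(abs(ends - c0) <= 1)
    nearby <- sum(abs(ends - c0) %in% 2:3)
    expect_gt(atCut, 50)
    expect_gt(atCut, 10 * max(nearby, 1))
})

test_that("binomial recovery: estimated efficiency is within 3 SD of a planted 0.5", {
    sim <- fixtureGenome()
    gd <- simulateGdna(sim$genome, sim$sites, fCut = 0.5, coverage = 10000,
                       seed = 21L)
    eff <- estimateEfficiency(gd$fragments, sim$genome, sim$sites,
                              seed = 22L)
    expect_lt(abs(fCut(eff) - 0.5), 3 * sigmaTotal(eff))
})

test_that("spike-in-only read sets have the expected total and facing strands", {
    sim <- fixtureGenome()
    rd <- simulateDsbReads(sim$genome, sim$sites, fCut = 0.3,
                           alpha = 1000, seed = 31L)
    expected <- 1000 * 0.3 * length(sim$sites)
    expect_lt(abs(length(rd$reads) - expected), 4 * sqrt(expected))
    ## every read 5' end is on a site vicinity, from both strands
    expect_identical(countReadsAtSites(rd$reads, sim$sites),
                     length(rd$reads))
    expect_gt(sum(strand(rd$reads) == "+"), 0)
    expect_gt(sum(strand(rd$reads) == "-"), 0)
})

test_that("one-ended landscape entries emit strictly single-strand signal", {
    sim <- fixtureGenome()
    lnd <- breakLandscape(
        oneEnded = data.frame(chrom = "chrA", pos = 75000L, freq = 0.5,
                              polarity = "+"))
    rd <- simulateDsbReads(sim$genome, sim$sites, fCut = 0,
                           landscape = lnd, alpha = 1000, seed = 32L)
    p5 <- read5p0(rd$reads)
    near <- abs(p5 - 75000) < 100
    expect_gt(sum(near), 0)
    expect_true(all(strand(rd$reads)[near] == "+"))
})

test_that("telomere-fraction reads match the CAC-repeat rule", {
    sim <- fixtureGenome()
    lnd <- breakLandscape(uniformBackground = 5 / 250000,
                          telomereReadFraction = 0.1)
    rd <- simulateDsbReads(sim$genome, sim$sites, fCut = 0.3,
                           landscape = lnd, alpha = 500, seed = 33L)
    seqs <- mcols(rd$reads)$seq
    telo <- isTelomericRead(seqs)
    expect_gt(sum(telo), 0)
    expect_equal(sum(telo) / length(rd$reads), 0.1, tolerance = 0.25)
})

test_that("UMI tables carry duplicates that exact-match dedup removes", {
    sites <- do.call(c, lapply(seq(10000, 100000, by = 10000), function(p)
        siteAt("chr1", p)))
    u <- simulateUmiReads(sites, dsbsPerCellPerSite = 0.01, nCells = 1000,
                          duplicationRate = 5, seed = 41L)
    ## ~100 breaks with ~6 copies each
    expect_gt(nrow(u$umis), 3 * u$truth$breaksActual)
    dd <- dedupUmis(u$umis)
    expect_lte(nrow(dd), u$truth$breaksActual)  # UMI collisions only shrink
    expect_gt(nrow(dd), 0.9 * u$truth$breaksActual)

    u0 <- simulateUmiReads(sites, 0.01, 1000, duplicationRate = 0,
                           seed = 42L)
    expect_identical(nrow(dedupUmis(u0$umis)), nrow(u0$umis))
})

test_that("unique UMI count scales with cell number at fixed per-cell rate", {
    sites <- do.call(c, lapply(seq(10000, 100000, by = 10000), function(p)
        siteAt("chr1", p)))
    u1 <- simulateUmiReads(sites, 0.02, 2000, seed = 43L)
    u2 <- simulateUmiReads(sites, 0.02, 4000, seed = 44L)
    r <- nrow(dedupUmis(u2$umis)) / nrow(dedupUmis(u1$umis))
    expect_equal(r, 2, tolerance = 0.15)
})
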