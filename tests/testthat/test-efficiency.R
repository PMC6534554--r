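test_that("fragment classification follows the end-in-vicinity / spanning rules", {
    site <- siteAt("chr1", 150L)
    ## spans the vicinity with both ends outside: uncut
    r <- classifyFragmentsAtSite(gr0("chr1", 100, 200), site, w = 3)
    expect_identical(c(r$nCut, r$nUncut), c(0L, 1L))
    ## right end at 151 falls inside 147..153: cut
    r <- classifyFragmentsAtSite(gr0("chr1", 100, 151), site, w = 3)
    expect_identical(c(r$nCut, r$nUncut), c(1L, 0L))
    ## no contact with the vicinity: ignored
    r <- classifyFragmentsAtSite(gr0("chr1", 100, 140), site, w = 3)
    expect_identical(c(r$nCut, r$nUncut), c(0L, 0L))
    ## overlaps the vicinity without an end inside and without spanning it
    r <- classifyFragmentsAtSite(gr0("chr1", 100, 146), site, w = 3)
    expect_identical(c(r$nCut, r$nUncut), c(0L, 0L))
    expect_error(classifyFragmentsAtSite(gr0("chr1", 1, 50), site, w = -1),
                 ">= 0")
})

test_that("vectorized classification agrees with the single-site rule", {
    set.seed(5)
    frags <- gr0("chr1", s <- sample.int(5000, 400), s + sample(30:500, 400,
                 replace = TRUE))
    sites <- c(siteAt("chr1", 1000L), siteAt("chr1", 1004L),
               siteAt("chr1", 3000L))
    fast <- countsAtSites(frags, sites, w = 3)
    for (i in seq_along(sites)) {
        slow <- classifyFragmentsAtSite(frags, sites[i], w = 3)
        expect_identical(fast$nCut[i], slow$nCut)
        expect_identical(fast$nUncut[i], slow$nUncut)
    }
})

test_that("site efficiency implements the two-fragments-per-cut estimator", {
    expect_equal(siteEfficiency(100, 50), 0.5)
    expect_equal(siteEfficiency(100, 0), 1.0)
    expect_equal(siteEfficiency(0, 50), 0)
    expect_warning(v <- siteEfficiency(0, 50, fBg = 0.1), "clamped")
    expect_equal(v, 0)
    expect_error(siteEfficiency(0, 0), "nCut \\+ nUncut")
})

test_that("site efficiency is monotone in its inputs", {
    f0 <- siteEfficiency(100, 100)
    expect_gt(siteEfficiency(150, 100), f0)
    expect_lt(siteEfficiency(100, 150), f0)
    expect_lt(siteEfficiency(100, 100, fBg = 0.05), f0)
})

test_that("pooled efficiency sums counts over passing sites only", {
    counts <- data.frame(chrom = "c", cutPos0 = c(1, 2),
                         nCut = c(100L, 300L), nUncut = c(50L, 150L))
    est <- pooledEfficiency(counts, fBg = 0)
    expect_equal(fCut(est), 0.5)  # 400 / (400 + 2*200)
    expect_identical(est@nSitesUsed, 2L)

    ## shallow site dropped by the depth filter
    counts2 <- rbind(counts, data.frame(chrom = "c", cutPos0 = 3,
                                        nCut = 6L, nUncut = 4L))
    est2 <- pooledEfficiency(counts2, fBg = 0)
    expect_identical(est2@nSitesUsed, 2L)
    expect_equal(fCut(est2), 0.5)
    expect_match(perSiteTable(est2)$reason[3], "classified fragments")

    ## deep site with zero efficiency dropped by the positivity filter
    counts3 <- rbind(counts, data.frame(chrom = "c", cutPos0 = 3,
                                        nCut = 0L, nUncut = 4000L))
    est3 <- pooledEfficiency(counts3, fBg = 0)
    expect_identical(est3@nSitesUsed, 2L)
    expect_match(perSiteTable(est3)$reason[3], "efficiency <= 0")

    expect_error(pooledEfficiency(
        data.frame(chrom = "c", cutPos0 = 1, nCut = 5L, nUncut = 5L)),
        "no site passes")
})

test_that("pooled efficiency equals site efficiency for a single passing site", {
    counts <- data.frame(chrom = "c", cutPos0 = 1,
                         nCut = 210L, nUncut = 140L)
    est <- pooledEfficiency(counts, fBg = 0.01)
    expect_equal(fCut(est), siteEfficiency(210, 140, fBg = 0.01))
})

test_that("Poisson SD matches the closed form and shrinks with depth", {
    expect_equal(poissonSD(100, 100), (110 / 290 - 90 / 310) / 2)
    expect_equal(poissonSD(100, 100), 0.0445, tolerance = 1e-3)
    expect_equal(poissonSD(1e6, 1e6), poissonSdOracle(1e6, 1e6))
    expect_lt(poissonSD(1e6, 1e6), 5e-4)
    ## fixed ratio, growing depth: SD tends to zero
    sds <- vapply(c(1e2, 1e4, 1e6), function(n) poissonSD(n, 2 * n),
                  numeric(1))
    expect_true(all(diff(sds) < 0))
    expect_error(poissonSD(1e4, 0), "too small")
})

test_that("background estimation matches an exhaustive-window oracle", {
    sim <- fixtureGenome()
    ## sonication-only library: everything the classifier sees is background
    gd <- simulateGdna(sim$genome, sim$sites[0], fCut = 0, coverage = 0,
                       sonicationRate = 0.05, seed = 51L)
    bg <- estimateBackground(gd$fragments, sim$genome, sites = sim$sites,
                             w = 3, nWindows = 1500, seed = 52L)
    ## oracle: deterministic dense grid of windows, longhand classification
    l0 <- start(gd$fragments) - 1L
    r0 <- end(gd$fragments)
    fchr <- as.character(seqnames(gd$fragments))
    grid <- expand.grid(chrom = names(sim$genome),
                        frac = seq(0.02, 0.98, by = 0.004))
    vals <- mapply(function(ch, fr) {
        c0 <- round(genomeLengths(sim$genome)[ch] * fr)
        sel <- fchr == ch
        cnt <- sum((l0[sel] >= c0 - 3 & l0[sel] <= c0 + 3) |
                   (r0[sel] >= c0 - 3 & r0[sel] <= c0 + 3))
        spn <- sum(l0[sel] < c0 - 3 & r0[sel] > c0 + 3)
        if (cnt + spn == 0) 0 else cnt / (cnt + 2 * spn)
    }, as.character(grid$chrom), grid$frac)
    oracleMean <- mean(vals)
    oracleSD <- sd(vals)
    expect_lt(abs(bg@fBg - oracleMean), 3 * oracleSD / sqrt(1500) + 1e-3)
    expect_equal(bg@sigmaBg, oracleSD, tolerance = 0.15)

    ## no fragments at all: background is exactly zero
    bg0 <- estimateBackground(gd$fragments[0], sim$genome, seed = 53L)
    expect_identical(bg0@fBg, 0)

    b1 <- estimateBackground(gd$fragments, sim$genome, seed = 54L)
    b2 <- estimateBackground(gd$fragments, sim$genome, seed = 54L)
    expect_identical(b1@fBg, b2@fBg)
})

test_that("qPCR efficiency follows 1 - 2^-dCT and averages dilutions", {
    expect_equal(qpcrEfficiency(21, 20), 0.5)
    expect_equal(qpcrEfficiency(20, 20), 0)
    expect_equal(qpcrEfficiency(23, 20), 0.875)
    expect_equal(qpcrEfficiency(c(21, 23), c(20, 20)), mean(c(0.5, 0.875)))
    expect_warning(v <- qpcrEfficiency(19, 20), "anomaly")
    expect_equal(v, 0)
    expect_error(qpcrEfficiency(-1, 20), "positive")
})

test_that("linearity check returns Pearson r with the weak-correlation flag", {
    eff <- c(0.1, 0.2, 0.3, 0.4)
    res <- linearityCheck(1000 * eff, eff)
    expect_equal(res$r, 1)
    expect_false(res$weak)
    expect_equal(res$slope, 1000)
    const <- linearityCheck(c(5, 5, 5), c(0.1, 0.2, 0.3))
    expect_true(is.na(const$r))
    expect_error(linearityCheck(1:2, 1:2), "at least 3")
})

test_that("planted efficiency is recovered within 3 sigma across replicates", {
    sim <- fixtureGenome()
    ok <- vapply(1:12, function(s) {
        f <- c(0.12, 0.3, 0.62)[(s %% 3) + 1]
        gd <- simulateGdna(sim$genome, sim$sites, fCut = f,
                           coverage = 2000, seed = 60 + s)
        eff <- estimateEfficiency(gd$fragments, sim$genome, sim$sites,
                                  seed = 160 + s)
        abs(fCut(eff) - f) <= 3 * sigmaTotal(eff)
    }, logical(1))
    expect_true(all(ok))
})
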