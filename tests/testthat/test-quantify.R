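test_that("spike-in break frequency is fCut * nSites * p", {
    expect_equal(spikeInBreaks(0.71, 1, 0.02), 0.0142)
    expect_equal(spikeInBreaks(0.5, 2, 1), 1)
    expect_error(spikeInBreaks(0.5, 2, 0), "p must")
    ## zero efficiency propagates to an explicit downstream error
    expect_equal(spikeInBreaks(0, 5, 1), 0)
    expect_error(quantifyDSBs(100, 50, spikeInBreaks(0, 5, 1)),
                 "alpha undefined")
})

test_that("reads are counted at sites by their 5' end with a tie rule", {
    site <- siteAt("chr1", 500L)
    expect_identical(countReadsAtSites(
        readsAt("chr1", rep(500L, 10), "+"), site, w = 3), 10L)
    ## boundary: cut + w counted, cut + w + 1 not
    expect_identical(countReadsAtSites(readsAt("chr1", 503L, "+"), site,
                                       w = 3), 1L)
    expect_identical(countReadsAtSites(readsAt("chr1", 504L, "+"), site,
                                       w = 3), 0L)
    ## minus-strand 5' end is the rightmost base
    expect_identical(countReadsAtSites(readsAt("chr1", 499L, "-"), site,
                                       w = 3), 1L)
    ## two sites 4 bp apart: a read between them counts once, at the
    ## nearer site; exact ties go to the lower coordinate
    two <- c(siteAt("chr1", 500L), siteAt("chr1", 504L))
    expect_identical(sum(countReadsAtSites(readsAt("chr1", 501L, "+"),
                                           two, w = 3, perSite = TRUE) *
                         c(1L, 10L)), 1L)
    expect_identical(sum(countReadsAtSites(readsAt("chr1", 502L, "+"),
                                           two, w = 3, perSite = TRUE) *
                         c(1L, 10L)), 1L)  # equidistant -> lower site
    expect_identical(sum(countReadsAtSites(readsAt("chr1", 503L, "+"),
                                           two, w = 3, perSite = TRUE) *
                         c(1L, 10L)), 10L)
})

test_that("telomeric reads are full-length CAC-repeat matches in either orientation", {
    expect_true(isTelomericRead("CACCACAC"))
    expect_false(isTelomericRead("ACGTACGT"))
    ## reverse complement of a telomeric sequence is telomeric too
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString("CACCACAC")))
    expect_true(isTelomericRead(rc))
    ## a partial match does not qualify: the whole read must be repeats
    expect_false(isTelomericRead("CACCACACGGGG"))
    expect_false(isTelomericRead(NA_character_))
    ## independent regex oracle on assorted strings
    strs <- c("ACAC", "CCCACC", "AAAA", "CACACACACA", "CCCCAC", "ACGT")
    expect_identical(isTelomericRead(strs),
                     grepl("^(C{0,3}AC{1,10})+$", strs, perl = TRUE) |
                     grepl("^(C{0,3}AC{1,10})+$", vapply(strs, function(s)
                         as.character(Biostrings::reverseComplement(
                             Biostrings::DNAString(s))), ""), perl = TRUE))
})

test_that("studied-read filtering removes site, telomere and mask reads once each", {
    site <- siteAt("chr1", 500L)
    reads <- c(readsAt("chr1", rep(500L, 10), "+", seq = "ACGTACGT"),
               readsAt("chr1", seq(2000, 2400, 100), "+",
                       seq = "CACCACAC"),
               readsAt("chr1", seq(5000, 5400, 100), "+",
                       seq = "ACGTACGT"),
               readsAt("chr1", seq(8000, 15900, 100), "+",
                       seq = "ACGTACGT"))
    mask <- gr0("chr1", 4900, 5600)
    res <- filterStudiedReads(reads, sites = site, w = 3, telomere = TRUE,
                              masks = mask)
    expect_identical(res$rStudied, 80L)
    aud <- setNames(res$audit$reads, res$audit$category)
    expect_identical(aud[["cut_site"]], 10L)
    expect_identical(aud[["telomere"]], 5L)
    expect_identical(aud[["mask"]], 5L)
    ## audit always accounts for input minus output
    expect_identical(sum(aud[c("cut_site", "telomere", "mask")]),
                     length(reads) - res$rStudied)

    ## priority: a telomeric read at a site counts as a site read
    telAtSite <- readsAt("chr1", 500L, "+", seq = "CACCACAC")
    res2 <- filterStudiedReads(telAtSite, sites = site, w = 3,
                               telomere = TRUE)
    aud2 <- setNames(res2$audit$reads, res2$audit$category)
    expect_identical(aud2[["cut_site"]], 1L)
    expect_identical(aud2[["telomere"]], 0L)
})

test_that("quantification follows alpha = Rcut/Bcut, Bstudied = Rstudied/alpha", {
    q <- quantifyDSBs(rStudied = 7650000, rCut = 710, bCut = 0.0142)
    expect_equal(alphaCoef(q), 50000)
    expect_equal(bStudied(q), 153)
    expect_equal(bStudied(quantifyDSBs(0, 710, 0.0142)), 0)
    ## scale invariance: doubling both read counts changes nothing
    q2 <- quantifyDSBs(2 * 7650000, 2 * 710, 0.0142)
    expect_equal(bStudied(q2), bStudied(q))
    expect_error(quantifyDSBs(100, 0, 0.5), "no spike-in signal")
})

test_that("per-site SD is the spread of single-site quantifications", {
    ## two sites engineered to yield 10 and 20 breaks/cell
    res <- perSiteSD(rCutPerSite = c(1000, 1000), fPerSite = c(0.1, 0.2),
                     p = 1, rStudied = 100000)
    expect_equal(res$perSiteB, c(10, 20))
    expect_equal(res$sd, sd(c(10, 20)))
    expect_equal(res$sd, 7.07, tolerance = 1e-3)
    expect_identical(res$method, "per_site")

    same <- perSiteSD(c(500, 500, 500), c(0.3, 0.3, 0.3), 1, 10000)
    expect_equal(same$sd, 0)

    ## single usable site: propagated from the efficiency uncertainty
    est <- pooledEfficiency(
        data.frame(chrom = "c", cutPos0 = 1, nCut = 300L, nUncut = 300L),
        fBg = 0)
    one <- perSiteSD(c(400), c(0.25), 1, 10000, efficiency = est)
    expect_identical(one$method, "propagated")
    expect_gt(one$sd, 0)
})

test_that("window density divides window read counts by alpha", {
    genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 2000)))
    reads <- readsAt("chr1", seq(0, 490, by = 10), "+")  # 50 reads
    tr <- windowDensity(reads, genome, alpha = 1000, window = 500,
                        step = 500)
    expect_equal(tr$score[1], 0.05)
    expect_equal(tr$score[2], 0)
    trM <- windowDensity(reads, genome, alpha = 1000, window = 500,
                         step = 500, scale = "per_million_cells")
    expect_equal(trM$score[1], 50000)
    ## conservation with step == window
    expect_equal(sum(tr$score) * 1000, length(reads))
})

test_that("sliding windows with a smaller step cover each read window/step times", {
    genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 5000)))
    reads <- readsAt("chr1", rep(2500L, 20), "+")
    tr <- windowDensity(reads, genome, alpha = 1, window = 500, step = 50)
    expect_equal(sum(tr$score), 20 * 10)
})

test_that("replication background removal subtracts the histogram mode", {
    tr <- GRanges("chr1", IRanges(seq(1, 2001, 500), width = 500),
                  score = c(2, 2, 2, 5, 2))
    out <- removeReplicationBackground(tr)
    expect_equal(out$background, 2)
    expect_equal(out$track$score, c(0, 0, 0, 3, 0))

    const <- GRanges("chr1", IRanges(seq(1, 1501, 500), width = 500),
                     score = rep(1.5, 4))
    expect_equal(removeReplicationBackground(const)$track$score,
                 rep(0, 4))
    expect_error(removeReplicationBackground(const[0]), "empty")
})

test_that("background recovery on a planted uniform baseline stays within a bin", {
    sim <- fixtureGenome()
    u <- 40 / 250000  # 40 breaks/cell spread uniformly
    lnd <- breakLandscape(
        twoEnded = data.frame(chrom = "chrA", pos = c(30000L, 90000L),
                              freq = 0.9),
        uniformBackground = u)
    rd <- simulateDsbReads(sim$genome, sim$sites, fCut = 0,
                           landscape = lnd, alpha = 2000, seed = 71L)
    tr <- windowDensity(rd$reads, sim$genome, alpha = 2000)
    out <- removeReplicationBackground(tr)
    expect_lte(abs(out$background - u * 500), out$binWidth)
    expect_true(all(out$track$score >= 0))
})

test_that("the Poisson 5-SD comparison flags windows above mean + 5 sqrt(mean)", {
    cmp <- compareSamplesPoisson(controlCounts = c(4, 4, 4),
                                 treatedCounts = c(15, 14, 4))
    expect_equal(cmp$threshold, rep(4 + 5 * 2, 3))
    expect_identical(cmp$enriched, c(TRUE, FALSE, FALSE))
    ## identical samples: nothing flagged
    same <- compareSamplesPoisson(c(5, 8, 13), c(5, 8, 13))
    expect_false(any(same$enriched))
})

test_that("a simulated global induction is flagged in nearly all windows", {
    ## a uniform 7-fold induction with matched spike-in normalization: the
    ## 5-SD rule flags essentially every window, while the depth-relative
    ## hypergeometric test sees nothing -- read-count normalization alone
    ## cannot detect global induction
    set.seed(81)
    n <- 400
    control <- rpois(n, 40)
    treated <- rpois(n, 7 * 40)
    cmp <- compareSamplesPoisson(control, treated)
    expect_gt(mean(cmp$enriched), 0.95)
    expect_false(any(cmp$pBonf < 0.05))
    ## the hypergeometric does flag relative (localized) enrichment
    local <- rpois(n, 40)
    local[5] <- 400
    cmpL <- compareSamplesPoisson(control, local)
    expect_lt(cmpL$pBonf[5], 0.05)
})

test_that("quantification is invariant to uniform read subsampling in expectation", {
    sim <- fixtureGenome()
    lnd <- breakLandscape(uniformBackground = 100 / 250000)
    deltas <- vapply(1:5, function(s) {
        rd <- simulateDsbReads(sim$genome, sim$sites, fCut = 0.3,
                               landscape = lnd, alpha = 2000,
                               seed = 90 + s)
        quantOf <- function(reads) {
            rCut <- countReadsAtSites(reads, sim$sites)
            filt <- filterStudiedReads(reads, sites = sim$sites,
                                       telomere = FALSE)
            bStudied(quantifyDSBs(filt$rStudied, rCut,
                                  spikeInBreaks(0.3, length(sim$sites))))
        }
        full <- quantOf(rd$reads)
        set.seed(1000 + s)
        thin <- rd$reads[runif(length(rd$reads)) < 0.1]
        (quantOf(thin) - full) / full
    }, numeric(1))
    expect_lt(abs(mean(deltas)), 0.05)
})
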