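## Shared fixture builders and independent oracles. Everything is built in
## code; no binary fixtures.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(Biostrings)
})

## GRanges from 0-based half-open coordinates (the frame most spec-style
## interval examples are written in)
gr0 <- function(chrom, start0, end0, strand = "*", ...) {
    GRanges(chrom, IRanges(start = start0 + 1L, end = end0),
            strand = strand, ...)
}

## width-1 cut-site GRanges at a 0-based cut coordinate
siteAt <- function(chrom, cut0, vicinity = 3L) {
    g <- GRanges(chrom, IRanges(cut0 + 1L, width = 1L))
    mcols(g)$enzyme <- "test"
    mcols(g)$motifStrand <- "+"
    mcols(g)$vicinity <- vicinity
    g
}

## stranded reads whose 5' ends sit at given 0-based coordinates
readsAt <- function(chrom, p5, strand, readLength = 50L, seq = NA) {
    strand <- rep_len(strand, length(p5))
    s0 <- ifelse(strand == "+", p5, p5 - readLength + 1L)
    g <- GRanges(chrom, IRanges(s0 + 1L, width = readLength),
                 strand = strand)
    mcols(g)$seq <- rep_len(seq, length(g))
    g
}

## a small genome with planted NotI sites, shared across tests
fixtureGenome <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateGenome(
                c(chrA = 150000L, chrB = 100000L),
                embed = list(list(enzyme = builtinEnzymes()$NotI, n = 6L)),
                seed = 101L)
        cache
    }
})

## --- independent oracles ----------------------------------------------------

## hypergeometric upper-tail P(X >= k) by direct enumeration of the
## probability mass (lchoose arithmetic, independent of phyper)
hyperTailOracle <- function(k, nSuccess, nFail, nDraw) {
    kk <- max(k, max(0, nDraw - nFail)):min(nDraw, nSuccess)
    kk <- kk[kk >= k]
    if (!length(kk)) return(0)
    sum(exp(lchoose(nSuccess, kk) + lchoose(nFail, nDraw - kk) -
            lchoose(nSuccess + nFail, nDraw)))
}

## Benjamini-Hochberg step-up, written out longhand
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    ranked <- p[o] * n / seq_len(n)
    ## enforce monotonicity from the largest rank down
    adj <- rev(cummin(rev(ranked)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
}

## Poisson-spread SD of the efficiency estimate, hand-coded from the
## formula's definition
poissonSdOracle <- function(nc, nu) {
    up <- (nc + sqrt(nc)) / ((nc + sqrt(nc)) + 2 * (nu - sqrt(nu)))
    dn <- (nc - sqrt(nc)) / ((nc - sqrt(nc)) + 2 * (nu + sqrt(nu)))
    0.5 * (up - dn)
}

blissSdOracle <- function(numi, ncell) {
    0.5 * ((numi + sqrt(numi)) / (ncell - sqrt(ncell)) -
           (numi - sqrt(numi)) / (ncell + sqrt(ncell)))
}
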