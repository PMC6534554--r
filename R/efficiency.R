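## Cutting-efficiency estimation from paired-end gDNA fragments.
##
## A fragment is classified at a cut site as CUT when either of its ends
## falls inside the counting vicinity [cut - w, cut + w] (the molecule was
## cleaved there, so a fragment terminus abuts the cut), and as UNCUT when
## it spans the whole vicinity with both ends outside (an intact molecule
## covering the site). The molecule-fraction estimator
## f = N_cut / (N_cut + 2 N_uncut) - f_bg
## follows from each cleaved molecule contributing two fragments while an
## intact one contributes a single spanning fragment.

.fragEnds0 <- function(fragments) {
    list(left = BiocGenerics::start(fragments) - 1L,
         right = BiocGenerics::end(fragments))
}

.countsOneSite <- function(left0, right0, c0, w) {
    lo <- c0 - w
    hi <- c0 + w
    endIn <- (left0 >= lo & left0 <= hi) | (right0 >= lo & right0 <= hi)
    spans <- left0 < lo & right0 > hi
    c(nCut = sum(endIn), nUncut = sum(spans & !endIn))
}

## Sorted-ends counting: with fragment widths larger than the vicinity span
## (guaranteed here; vicinities are a few bp, fragments tens of bp), no
## fragment has both ends inside one vicinity, and every fragment whose
## right end is left of the vicinity also starts left of it. Then per
## vicinity [lo, hi]:
##   nCut   = #left in [lo,hi] + #right in [lo,hi]
##   nUncut = #{left < lo} - #{right <= hi}
## each computable from sorted end vectors by binary search.
## vectorized over c0
.countsSorted <- function(sortedL, sortedR, c0, w) {
    lo <- c0 - w
    hi <- c0 + w
    nLle <- findInterval(hi, sortedL)          # left <= hi
    nLlt <- findInterval(lo - 1, sortedL)      # left <  lo
    nRle <- findInterval(hi, sortedR)          # right <= hi
    nRlt <- findInterval(lo - 1, sortedR)      # right <  lo
    cbind(nCut = (nLle - nLlt) + (nRle - nRlt),
          nUncut = pmax(nLlt - nRle, 0L))
}

#' Classify gDNA fragments at a single cut site
#'
#' @param fragments \code{GRanges} of paired-end gDNA fragments.
#' @param site a single cut site (width-1 \code{GRanges} row).
#' @param w vicinity half-width in bp.
#' @return data.frame with one row: \code{nCut}, \code{nUncut}.
#' @examples
#' fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' st <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 151))
#' classifyFragmentsAtSite(fr, st, w = 3)  # spans the vicinity: uncut
#' @export
classifyFragmentsAtSite <- function(fragments, site, w = 3L) {
    if (w < 0) stop("w must be >= 0")
    stopifnot(length(site) == 1L)
    countsAtSites(fragments, site, w = w)
}

## per-chromosome index: sorted end vectors for long fragments, raw ends
## for fragments short enough to defeat the sorted shortcut
.fragIndex <- function(fragments, w) {
    ends <- .fragEnds0(fragments)
    fchr <- as.character(GenomicRanges::seqnames(fragments))
    len <- ends$right - ends$left
    short <- len <= 2L * w + 1L
    lapply(split(seq_along(fchr), fchr), function(idx) {
        s <- idx[short[idx]]
        l <- idx[!short[idx]]
        ## stored as doubles: findInterval coerces (and copies) integer
        ## vectors on every call otherwise
        list(sortedL = as.double(sort(ends$left[l])),
             sortedR = as.double(sort(ends$right[l])),
             shortL = ends$left[s], shortR = ends$right[s])
    })
}

## vectorized over c0; returns a matrix with nCut/nUncut columns
.countsIndexed <- function(index, ch, c0, w) {
    ix <- index[[ch]]
    if (is.null(ix))
        return(cbind(nCut = rep(0L, length(c0)),
                     nUncut = rep(0L, length(c0))))
    cnt <- .countsSorted(ix$sortedL, ix$sortedR, c0, w)
    if (length(ix$shortL))
        cnt <- cnt + t(vapply(c0, function(x)
            .countsOneSite(ix$shortL, ix$shortR, x, w),
            c(nCut = 0L, nUncut = 0L)))
    cnt
}

#' Classify gDNA fragments at each cut site
#'
#' Vectorized cut/uncut classification; each fragment is counted at most
#' once per site, and fragments overlapping a vicinity without satisfying
#' either rule are ignored.
#'
#' @param fragments \code{GRanges} of gDNA fragments.
#' @param sites cut-site \code{GRanges}.
#' @param w vicinity half-width in bp.
#' @return data.frame with one row per site: \code{chrom}, \code{cutPos0},
#'   \code{nCut}, \code{nUncut}.
#' @export
countsAtSites <- function(fragments, sites, w = 3L) {
    if (w < 0) stop("w must be >= 0")
    index <- .fragIndex(fragments, w)
    schr <- as.character(GenomicRanges::seqnames(sites))
    c0 <- cutPos0(sites)
    out <- matrix(0L, nrow = length(sites), ncol = 2,
                  dimnames = list(NULL, c("nCut", "nUncut")))
    for (ch in unique(schr)) {
        i <- which(schr == ch)
        out[i, ] <- .countsIndexed(index, ch, c0[i], w)
    }
    data.frame(chrom = schr, cutPos0 = c0,
               nCut = out[, "nCut"], nUncut = out[, "nUncut"])
}

#' Single-site cutting efficiency
#'
#' \code{nCut / (nCut + 2 nUncut) - fBg}, clamped to \[0, 1\]. The factor 2
#' reflects that a cleaved molecule is observed as two fragments.
#'
#' @param nCut number of cut-classified fragments.
#' @param nUncut number of spanning (uncut) fragments.
#' @param fBg background efficiency to subtract.
#' @return efficiency in \[0, 1\].
#' @examples
#' siteEfficiency(100, 50)  # 0.5
#' @export
siteEfficiency <- function(nCut, nUncut, fBg = 0) {
    if (nCut + nUncut <= 0)
        stop("no fragments classified at site (nCut + nUncut == 0)")
    f <- nCut / (nCut + 2 * nUncut) - fBg
    if (f < 0) {
        warning("negative efficiency after background subtraction; ",
                "clamped to 0")
        f <- 0
    }
    min(f, 1)
}

#' Poisson SD of a cutting-efficiency estimate
#'
#' Half-spread of the efficiency when the cut and uncut counts are each
#' perturbed by one Poisson standard deviation in opposite directions:
#' \deqn{\frac12\Big(
#'   \frac{N_c+\sqrt{N_c}}{(N_c+\sqrt{N_c})+2(N_u-\sqrt{N_u})} -
#'   \frac{N_c-\sqrt{N_c}}{(N_c-\sqrt{N_c})+2(N_u+\sqrt{N_u})}\Big)}
#'
#' @param nCut,nUncut fragment counts, both >= 1 (the approximation is
#'   undefined below that).
#' @return SD of the efficiency estimate.
#' @examples
#' poissonSD(100, 100)  # 0.0445
#' @export
poissonSD <- function(nCut, nUncut) {
    if (nCut < 1 || nUncut < 1)
        stop("counts too small for the Poisson approximation ",
             "(need nCut >= 1 and nUncut >= 1)")
    sc <- sqrt(nCut)
    su <- sqrt(nUncut)
    hi <- (nCut + sc) / ((nCut + sc) + 2 * (nUncut - su))
    lo <- (nCut - sc) / ((nCut - sc) + 2 * (nUncut + su))
    (hi - lo) / 2
}

#' Pooled multi-site cutting efficiency
#'
#' Sums cut and uncut counts over sites passing the depth and positivity
#' filters (more than \code{minReads} classified fragments and a per-site
#' efficiency above zero after background subtraction), then applies the
#' single-site formula to the pooled counts.
#'
#' @param counts per-site counts from [countsAtSites()].
#' @param fBg background efficiency (scalar) or a
#'   [BackgroundEstimate-class].
#' @param sigmaBg SD of \code{fBg}; taken from the object when \code{fBg} is
#'   a \code{BackgroundEstimate}.
#' @param minReads per-site minimum classified-fragment count (default 100).
#' @return an [EfficiencyEstimate-class]; \code{perSiteTable()} retains all
#'   sites with pass/fail flags and reasons.
#' @export
pooledEfficiency <- function(counts, fBg = 0, sigmaBg = 0, minReads = 100) {
    if (is(fBg, "BackgroundEstimate")) {
        sigmaBg <- fBg@sigmaBg
        fBg <- fBg@fBg
    }
    tot <- counts$nCut + counts$nUncut
    fRaw <- ifelse(tot > 0, counts$nCut / (counts$nCut + 2 * counts$nUncut),
                   NA_real_)
    fSite <- fRaw - fBg
    passDepth <- tot > minReads
    passPos <- !is.na(fSite) & fSite > 0
    pass <- passDepth & passPos
    reason <- rep("", nrow(counts))
    reason[!passDepth] <- sprintf("<= %g classified fragments", minReads)
    reason[passDepth & !passPos] <- "efficiency <= 0 after background"
    perSite <- cbind(counts,
                     data.frame(fSite = fSite, pass = pass, reason = reason))
    if (!any(pass))
        stop("no site passes the pooling filters (> ", minReads,
             " classified fragments and efficiency > 0)")
    NC <- sum(counts$nCut[pass])
    NU <- sum(counts$nUncut[pass])
    f <- max(0, min(1, NC / (NC + 2 * NU) - fBg))
    sp <- if (NC >= 1 && NU >= 1) poissonSD(NC, NU) else NA_real_
    new("EfficiencyEstimate", fCut = f,
        sigmaPoisson = sp, sigmaBg = sigmaBg,
        sigmaTotal = sqrt(sp^2 + sigmaBg^2),
        perSite = perSite, nSitesUsed = sum(pass))
}

#' Estimate background cutting efficiency from random windows
#'
#' Samples windows of the same size as the site-counting vicinity at random
#' genomic positions away from real cut sites, applies the cut/uncut
#' classifier with a pseudo-site at each window center, and summarizes the
#' per-window apparent efficiencies. Windows with no classified fragments
#' score zero.
#'
#' @param fragments gDNA fragment \code{GRanges}.
#' @param genome \code{DNAStringSet}.
#' @param sites cut-site \code{GRanges} whose surroundings (vicinity plus
#'   one fragment length) are excluded from sampling; \code{NULL} for none.
#' @param w vicinity half-width (must equal the one used at sites).
#' @param nWindows number of windows (default 1500, within the conventional
#'   1000-2000 range).
#' @param maxFragLen exclusion margin around sites (default 800 bp, above
#'   the longest simulated fragment).
#' @param seed RNG seed.
#' @return a [BackgroundEstimate-class].
#' @export
estimateBackground <- function(fragments, genome, sites = NULL, w = 3L,
                               nWindows = 1500L, maxFragLen = 800L,
                               seed = 1L) {
    set.seed(seed)
    lens <- genomeLengths(genome)
    if (any(lens < 2L * (2L * w + 1L)))
        stop("genome shorter than the background window size")
    index <- .fragIndex(fragments, w)
    schr <- if (!is.null(sites))
        as.character(GenomicRanges::seqnames(sites)) else character()
    sc0 <- if (!is.null(sites)) cutPos0(sites) else integer()

    margin <- maxFragLen
    usable <- names(lens)[lens > 2L * margin]
    if (!length(usable))
        stop("no chromosome long enough for background windows")
    winChr <- character(0)
    winC0 <- integer(0)
    guard <- 0L
    while (length(winC0) < nWindows) {
        guard <- guard + 1L
        if (guard > 100L)
            stop("cannot place background windows away from cut sites")
        need <- nWindows - length(winC0)
        ch <- sample(usable, 2L * need, replace = TRUE,
                     prob = lens[usable])
        c0 <- vapply(ch, function(x)
            sample.int(lens[x] - 2L * margin, 1) + margin, integer(1))
        ok <- vapply(seq_along(ch), function(i)
            !any(schr == ch[i] & abs(sc0 - c0[i]) <= w + maxFragLen),
            logical(1))
        winChr <- c(winChr, ch[ok])
        winC0 <- c(winC0, c0[ok])
    }
    winChr <- winChr[seq_len(nWindows)]
    winC0 <- winC0[seq_len(nWindows)]
    vals <- numeric(nWindows)
    for (ch in unique(winChr)) {
        i <- which(winChr == ch)
        cnt <- .countsIndexed(index, ch, winC0[i], w)
        tot <- cnt[, "nCut"] + cnt[, "nUncut"]
        vals[i] <- ifelse(tot > 0,
                          cnt[, "nCut"] / (cnt[, "nCut"] + 2 * cnt[, "nUncut"]),
                          0)
    }
    new("BackgroundEstimate", fBg = mean(vals), sigmaBg = stats::sd(vals),
        nWindows = as.integer(nWindows), windowSize = as.integer(2L * w + 1L),
        seed = as.integer(seed))
}

#' Cutting efficiency from qPCR threshold cycles
#'
#' \code{f = 1 - 2^(-dCT)} with \code{dCT = ctTreated - ctUntreated +
#' calibrationOffset}; several dilutions are averaged. Negative dCT values
#' (amplification anomalies) are clamped to zero with a warning.
#'
#' @param ctTreated,ctUntreated threshold cycles per dilution.
#' @param calibrationOffset empirical per-dilution dCT correction.
#' @return mean cutting efficiency across dilutions.
#' @examples
#' qpcrEfficiency(21, 20)  # dCT = 1 -> 0.5
#' @export
qpcrEfficiency <- function(ctTreated, ctUntreated, calibrationOffset = 0) {
    stopifnot(length(ctTreated) == length(ctUntreated))
    if (any(ctTreated <= 0) || any(ctUntreated <= 0))
        stop("threshold cycles must be positive")
    dct <- ctTreated - ctUntreated + calibrationOffset
    if (any(dct < 0)) {
        warning("negative delta-CT clamped to 0 (amplification anomaly)")
        dct <- pmax(dct, 0)
    }
    mean(1 - 2^(-dct))
}

#' Linearity between labeled reads and cutting efficiencies
#'
#' Pearson correlation and least-squares fit of per-site labeled read counts
#' against per-site cutting efficiencies. Quantification is reliable when
#' the two are proportional; a correlation at or below 0.5 flags a
#' problematic (too low or too high) cutting-efficiency regime.
#'
#' @param labeledReads per-site labeled read counts.
#' @param efficiencies per-site cutting efficiencies.
#' @return list with \code{r}, \code{slope}, \code{intercept}, \code{n} and
#'   logical \code{weak} (\code{r <= 0.5}); \code{r} is \code{NA} for a
#'   constant input vector.
#' @export
linearityCheck <- function(labeledReads, efficiencies) {
    stopifnot(length(labeledReads) == length(efficiencies))
    if (length(labeledReads) < 3)
        stop("need at least 3 sites for a linearity check")
    if (stats::sd(labeledReads) == 0 || stats::sd(efficiencies) == 0)
        return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                    n = length(labeledReads), weak = NA))
    r <- stats::cor(labeledReads, efficiencies)
    fit <- stats::lm(labeledReads ~ efficiencies)
    list(r = r,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         n = length(labeledReads),
         weak = r <= 0.5)
}
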