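## Spike-in calibrated conversion of labeled read counts into absolute DSB
## frequencies per cell:
##   B_cut = f_cut * N_sites * p        (spike-in breaks per cell)
##   alpha = R_cut / B_cut              (labeled reads per break)
##   B_studied = R_studied / alpha      (studied breaks per cell)

#' Read 5' end coordinates (0-based)
#'
#' Proximal-barcode reads start at the break, so the 5' end is the
#' break-proximal base: the leftmost base for Watson reads, the rightmost
#' for Crick reads.
#'
#' @param reads stranded \code{GRanges}.
#' @return integer vector of 0-based 5'-end coordinates.
#' @export
read5p0 <- function(reads) {
    str <- as.character(GenomicRanges::strand(reads))
    ifelse(str == "-", BiocGenerics::end(reads) - 1L,
           BiocGenerics::start(reads) - 1L)
}

#' Spike-in breaks per cell
#'
#' \code{bCut = fCut * nSites * p}: cutting efficiency times number of
#' restriction sites times the proportion of digested cells.
#'
#' @param fCut cutting efficiency (numeric or an
#'   [EfficiencyEstimate-class]).
#' @param nSites number of enzyme cutting sites used.
#' @param p proportion of digested cells in (0, 1]; 1 unless a digested
#'   construct was mixed in.
#' @return spike-in DSBs per cell.
#' @examples
#' spikeInBreaks(0.71, 1, 0.02)  # 0.0142
#' @export
spikeInBreaks <- function(fCut, nSites, p = 1) {
    if (is(fCut, "EfficiencyEstimate")) fCut <- fCut@fCut
    if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
    if (fCut < 0 || fCut > 1) stop("fCut must lie in [0, 1]")
    fCut * nSites * p
}

.assignToSites <- function(p5, chr, sites, w) {
    ## nearest site per read (ties -> lower coordinate); NA when farther
    ## than w. Returns site index per read.
    schr <- as.character(GenomicRanges::seqnames(sites))
    c0 <- cutPos0(sites)
    out <- rep(NA_integer_, length(p5))
    for (ch in unique(schr)) {
        si <- which(schr == ch)
        sc <- c0[si]
        o <- order(sc)
        si <- si[o]
        sc <- sc[o]
        ri <- which(chr == ch)
        if (!length(ri)) next
        pos <- p5[ri]
        k <- findInterval(pos, sc)
        lo <- pmax(k, 1L)
        hi <- pmin(k + 1L, length(sc))
        dlo <- abs(pos - sc[lo])
        dhi <- abs(pos - sc[hi])
        ## strict '<' keeps the lower-coordinate site on ties
        best <- ifelse(dhi < dlo, hi, lo)
        dist <- pmin(dlo, dhi)
        hit <- dist <= w
        out[ri[hit]] <- si[best[hit]]
    }
    out
}

#' Count labeled reads at enzyme cutting sites
#'
#' A read is counted when its 5' end lies within \code{[cut - w, cut + w]}
#' of a site; each read is assigned to at most one site (the nearest, lower
#' coordinate on ties).
#'
#' @param reads stranded \code{GRanges}.
#' @param sites cut-site \code{GRanges}.
#' @param w vicinity half-width (default 3).
#' @param perSite return the per-site count vector instead of the total.
#' @return total count, or integer vector per site.
#' @export
countReadsAtSites <- function(reads, sites, w = 3L, perSite = FALSE) {
    asg <- .assignToSites(read5p0(reads),
                          as.character(GenomicRanges::seqnames(reads)),
                          sites, w)
    if (!perSite) return(sum(!is.na(asg)))
    tabulate(asg[!is.na(asg)], nbins = length(sites))
}

.telomerePattern <- "^(C{0,3}AC{1,10})+$"

#' Identify telomeric reads by the CAC-repeat rule
#'
#' A read is telomeric when its whole sequence (or its reverse complement,
#' i.e. the AC-rich strand) is a chain of \code{C{0,3}AC{1,10}} units.
#'
#' @param seqs character vector of read sequences (\code{NA} allowed, never
#'   telomeric).
#' @return logical vector.
#' @examples
#' isTelomericRead(c("CACCACAC", "ACGTACGT"))
#' @export
isTelomericRead <- function(seqs) {
    out <- rep(FALSE, length(seqs))
    ok <- !is.na(seqs) & nchar(seqs) > 0
    if (any(ok)) {
        fwd <- grepl(.telomerePattern, seqs[ok], perl = TRUE)
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(seqs[ok][!fwd])))
        rev <- grepl(.telomerePattern, rc, perl = TRUE)
        hit <- fwd
        hit[!fwd] <- rev
        out[ok] <- hit
    }
    out
}

#' Filter labeled reads down to studied-break reads
#'
#' Removes, in priority order, (i) reads counted at enzyme cutting sites,
#' (ii) telomeric reads by the CAC-repeat rule, (iii) reads overlapping
#' rDNA or custom mask intervals; every read is removed at most once and the
#' audit table accounts for each category.
#'
#' @param reads stranded \code{GRanges}, with a \code{seq} metadata column
#'   when telomere filtering is on.
#' @param sites cut-site \code{GRanges} (or \code{NULL}).
#' @param w vicinity half-width for site assignment.
#' @param telomere apply the telomeric-read filter.
#' @param masks \code{GRanges} of masked intervals (rDNA etc.), or a named
#'   list of such.
#' @return list with \code{reads} (retained \code{GRanges}),
#'   \code{rStudied} (retained count) and \code{audit} (data.frame of
#'   removed counts per category; input minus output equals the audit sum).
#' @export
filterStudiedReads <- function(reads, sites = NULL, w = 3L,
                               telomere = TRUE, masks = NULL) {
    n <- length(reads)
    atSite <- rep(FALSE, n)
    if (!is.null(sites) && length(sites)) {
        asg <- .assignToSites(read5p0(reads),
                              as.character(GenomicRanges::seqnames(reads)),
                              sites, w)
        atSite <- !is.na(asg)
    }
    telo <- rep(FALSE, n)
    if (telomere) {
        if (is.null(mcols(reads)$seq))
            stop("telomere filtering requested but reads carry no 'seq'")
        telo <- isTelomericRead(mcols(reads)$seq)
    }
    masked <- rep(FALSE, n)
    if (!is.null(masks)) {
        if (is.list(masks)) masks <- do.call(c, unname(masks))
        masked <- IRanges::overlapsAny(reads, masks, ignore.strand = TRUE)
    }
    remSite <- atSite
    remTelo <- telo & !remSite
    remMask <- masked & !remSite & !remTelo
    keep <- !(remSite | remTelo | remMask)
    audit <- data.frame(
        category = c("cut_site", "telomere", "mask", "retained"),
        reads = c(sum(remSite), sum(remTelo), sum(remMask), sum(keep)))
    list(reads = reads[keep], rStudied = sum(keep), audit = audit)
}

#' Convert read counts to studied DSBs per cell
#'
#' @param rStudied labeled reads from studied breaks (after filtering).
#' @param rCut labeled reads at cutting sites.
#' @param bCut spike-in breaks per cell from [spikeInBreaks()].
#' @param sdB optional SD of the estimate (see [perSiteSD()]).
#' @param sdMethod how \code{sdB} was obtained.
#' @return a [QuantResult-class].
#' @examples
#' quantifyDSBs(rStudied = 7650000, rCut = 710, bCut = 0.0142)
#' @export
quantifyDSBs <- function(rStudied, rCut, bCut, sdB = NA_real_,
                         sdMethod = "none") {
    if (bCut <= 0) stop("bCut must be positive (zero cutting efficiency ",
                        "leaves alpha undefined)")
    if (rCut <= 0) stop("no spike-in signal (rCut == 0)")
    if (rStudied < 0) stop("rStudied must be >= 0")
    alpha <- rCut / bCut
    new("QuantResult", bCut = bCut, rCut = rCut, alpha = alpha,
        rStudied = rStudied, bStudied = rStudied / alpha,
        sdB = sdB, sdMethod = sdMethod)
}

#' Per-site SD of the studied-break estimate
#'
#' Quantifies the studied breaks independently from each cutting site
#' (\code{alpha_i = rCut_i / (fSite_i * p)}) and returns the SD across
#' sites, a deliberately conservative spread. With fewer than two usable
#' sites the SD is propagated from the efficiency uncertainty instead
#' (relative SD of \code{fCut} times \code{bStudied}).
#'
#' @param rCutPerSite per-site labeled read counts
#'   (\code{countReadsAtSites(..., perSite = TRUE)}).
#' @param fPerSite per-site cutting efficiencies (background-subtracted).
#' @param p proportion of digested cells.
#' @param rStudied studied read count.
#' @param efficiency [EfficiencyEstimate-class], used for the propagated
#'   fallback.
#' @return list with \code{sd}, \code{method} (\code{"per_site"} or
#'   \code{"propagated"}) and \code{perSiteB} (per-site break estimates).
#' @export
perSiteSD <- function(rCutPerSite, fPerSite, p = 1, rStudied,
                      efficiency = NULL) {
    use <- !is.na(fPerSite) & fPerSite > 0 & rCutPerSite > 0
    perB <- rep(NA_real_, length(fPerSite))
    perB[use] <- rStudied * fPerSite[use] * p / rCutPerSite[use]
    if (sum(use) >= 2)
        return(list(sd = stats::sd(perB[use]), method = "per_site",
                    perSiteB = perB))
    if (is.null(efficiency) || efficiency@fCut <= 0)
        stop("fewer than 2 usable sites and no EfficiencyEstimate ",
             "to propagate from")
    nSites <- nrow(efficiency@perSite)
    b <- rStudied * efficiency@fCut * nSites * p /
        sum(rCutPerSite)
    list(sd = b * efficiency@sigmaTotal / efficiency@fCut,
         method = "propagated", perSiteB = perB)
}

#' Sliding-window DSB density track
#'
#' Counts filtered read 5' ends in sliding windows (default 500 bp window,
#' 50 bp step) and converts to breaks per cell (or per million cells) by
#' dividing by \code{alpha}.
#'
#' @param reads stranded \code{GRanges} (already filtered).
#' @param genome \code{DNAStringSet}.
#' @param alpha labeled reads per DSB.
#' @param window,step window size and step in bp.
#' @param scale \code{"per_cell"} or \code{"per_million_cells"}.
#' @return \code{GRanges} track with a \code{score} column.
#' @export
windowDensity <- function(reads, genome, alpha, window = 500L, step = 50L,
                          scale = c("per_cell", "per_million_cells")) {
    scale <- match.arg(scale)
    if (alpha <= 0) stop("alpha must be positive")
    lens <- genomeLengths(genome)
    p5 <- read5p0(reads)
    chr <- as.character(GenomicRanges::seqnames(reads))
    out <- vector("list", length(lens))
    for (i in seq_along(lens)) {
        ch <- names(lens)[i]
        if (lens[ch] < window) next
        starts0 <- seq.int(0L, lens[ch] - window, by = step)
        pos <- sort(p5[chr == ch])
        cnt <- findInterval(starts0 + window - 0.5, pos) -
            findInterval(starts0 - 0.5, pos)
        val <- cnt / alpha
        if (scale == "per_million_cells") val <- val * 1e6
        out[[i]] <- GenomicRanges::GRanges(
            seqnames = ch,
            ranges = IRanges::IRanges(start = starts0 + 1L,
                                      width = window),
            score = val, seqinfo = .genomeSeqinfo(genome))
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out))
        return(GenomicRanges::GRanges(seqinfo = .genomeSeqinfo(genome),
                                      score = numeric()))
    do.call(c, out)
}

#' Remove the replication (modal) background from a density track
#'
#' Estimates the background as the peak of the per-window value
#' distribution (histogram with Freedman-Diaconis bin widths, ties resolved
#' to the lowest bin, mode taken as the median of the values in the modal
#' bin), subtracts it everywhere and clamps negative values to zero.
#'
#' @param track \code{GRanges} with a \code{score} column.
#' @return list with \code{track} (corrected), \code{background} (the
#'   subtracted mode) and \code{binWidth} (the histogram resolution of the
#'   mode estimate).
#' @export
removeReplicationBackground <- function(track) {
    if (!length(track)) stop("empty track")
    v <- track$score
    uv <- sort(unique(v))
    if (length(uv) == 1L) {
        mode <- v[1]
        bw <- 0
    } else {
        ## Freedman-Diaconis width, floored at the value lattice: window
        ## counts divided by alpha live on a discrete grid, and bins finer
        ## than the grid make the histogram mode meaningless
        lattice <- min(diff(uv))
        bw <- max(2 * stats::IQR(v) / length(v)^(1 / 3), lattice)
        breaks <- seq(min(v) - bw / 2, max(v) + bw, by = bw)
        bin <- findInterval(v, breaks)
        counts <- tabulate(bin, nbins = length(breaks))
        b <- which.max(counts)  # which.max takes the first (lowest) tie
        mode <- stats::median(v[bin == b])
    }
    track$score <- pmax(v - mode, 0)
    list(track = track, background = mode, binWidth = bw)
}

#' Compare break levels between two samples with a Poisson 5-SD rule
#'
#' Treated per-window counts are first normalized onto the control sample's
#' read-per-break scale via the two spike-in coefficients; a window is
#' flagged enriched when the normalized treated count exceeds the control
#' count by more than \code{kSd} Poisson SDs. A one-sided hypergeometric
#' p-value with Bonferroni correction is reported alongside.
#'
#' @param controlCounts,treatedCounts per-window read counts (numeric
#'   vectors over identical windows).
#' @param alphaControl,alphaTreated reads-per-break coefficients of the two
#'   samples.
#' @param kSd Poisson SD multiplier (default 5, very conservative).
#' @return data.frame with columns \code{control}, \code{treatedAdj},
#'   \code{threshold}, \code{enriched}, \code{fold}, \code{pHyper},
#'   \code{pBonf}.
#' @export
compareSamplesPoisson <- function(controlCounts, treatedCounts,
                                  alphaControl = 1, alphaTreated = 1,
                                  kSd = 5) {
    stopifnot(length(controlCounts) == length(treatedCounts))
    adj <- treatedCounts * alphaControl / alphaTreated
    thr <- controlCounts + kSd * sqrt(controlCounts)
    enriched <- adj > thr
    Tc <- sum(controlCounts)
    Tt <- sum(treatedCounts)
    pHyper <- stats::phyper(treatedCounts - 1, Tt, Tc,
                            treatedCounts + controlCounts,
                            lower.tail = FALSE)
    pBonf <- pmin(pHyper * length(controlCounts), 1)
    fold <- ifelse(controlCounts > 0, adj / controlCounts, NA_real_)
    data.frame(control = controlCounts, treatedAdj = adj, threshold = thr,
               enriched = enriched, fold = fold,
               pHyper = pHyper, pBonf = pBonf)
}
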