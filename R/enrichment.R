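## Fragile-region detection (treatment vs control, hypergeometric with BH
## correction) and annotation enrichment with a length-preserving
## permutation null over mappable space.

#' Detect fragile regions from treatment vs control read counts
#'
#' Tiles the mappable genome, counts read 5' ends per window in both
#' samples, computes a one-sided hypergeometric p-value for treatment
#' enrichment per window (urn: all reads; successes: treatment reads) and
#' applies Benjamini-Hochberg correction across windows.
#'
#' @param treated,control stranded \code{GRanges} read sets on the same
#'   genome.
#' @param genome \code{DNAStringSet}.
#' @param window window size in bp (default 5000).
#' @param mappable optional \code{GRanges} of mappable intervals; windows
#'   not fully mappable are dropped. Default: everything mappable.
#' @param qThreshold BH-corrected significance threshold (default 0.05).
#' @return \code{GRanges} of all tested windows with metadata
#'   \code{treated}, \code{control}, \code{fold} (depth-normalized),
#'   \code{pValue}, \code{qValue}, \code{significant}.
#' @export
fragileRegions <- function(treated, control, genome, window = 5000L,
                           mappable = NULL, qThreshold = 0.05) {
    if (!length(control)) stop("empty control sample")
    lens <- genomeLengths(genome)
    countIn <- function(reads, gr) {
        p5 <- read5p0(reads)
        pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                                      IRanges::IRanges(p5 + 1L, width = 1L))
        GenomicRanges::countOverlaps(gr, pts, ignore.strand = TRUE)
    }
    tiles <- do.call(c, lapply(names(lens), function(ch) {
        nwin <- floor(lens[ch] / window)
        if (nwin == 0L) return(NULL)
        GenomicRanges::GRanges(
            seqnames = ch,
            ranges = IRanges::IRanges(
                start = (seq_len(nwin) - 1L) * window + 1L,
                width = window),
            seqinfo = .genomeSeqinfo(genome))
    }))
    if (!is.null(mappable)) {
        map <- GenomicRanges::reduce(mappable, ignore.strand = TRUE)
        ovl <- GenomicRanges::findOverlaps(tiles, map)
        q <- S4Vectors::queryHits(ovl)
        s <- S4Vectors::subjectHits(ovl)
        ovw <- pmin(BiocGenerics::end(tiles)[q], BiocGenerics::end(map)[s]) -
            pmax(BiocGenerics::start(tiles)[q],
                 BiocGenerics::start(map)[s]) + 1L
        wsum <- rep(0L, length(tiles))
        agg <- tapply(ovw, q, sum)
        wsum[as.integer(names(agg))] <- as.integer(agg)
        tiles <- tiles[wsum == window]
    }
    t <- countIn(treated, tiles)
    c <- countIn(control, tiles)
    Tt <- sum(t)
    Tc <- sum(c)
    p <- stats::phyper(t - 1, Tt, Tc, t + c, lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    fold <- ifelse(c > 0, (t / Tt) / (c / Tc), NA_real_)
    mcols(tiles)$treated <- t
    mcols(tiles)$control <- c
    mcols(tiles)$fold <- fold
    mcols(tiles)$pValue <- p
    mcols(tiles)$qValue <- q
    mcols(tiles)$significant <- q < qThreshold
    tiles
}

.mappableSpace <- function(genome, mappable) {
    if (is.null(mappable)) {
        lens <- genomeLengths(genome)
        mappable <- GenomicRanges::GRanges(
            seqnames = names(lens),
            ranges = IRanges::IRanges(1L, lens),
            seqinfo = .genomeSeqinfo(genome))
    }
    GenomicRanges::reduce(mappable, ignore.strand = TRUE)
}

.overlapBp <- function(a, b) {
    if (!length(a) || !length(b)) return(0)
    sum(as.numeric(BiocGenerics::width(
        GenomicRanges::intersect(a, b, ignore.strand = TRUE))))
}

#' Annotation enrichment of regions with a permutation null
#'
#' Observed statistic: the fraction of mappable nucleotides inside the
#' regions that fall in the annotation, divided by the fraction of mappable
#' genome nucleotides that fall in the annotation. The null distribution is
#' built by re-placing the regions (length-preserving) uniformly within
#' mappable space; the empirical p-value is
#' \code{(1 + #\{null >= observed\}) / (1 + nPerm)}.
#'
#' @param regions \code{GRanges} (e.g. significant fragile regions).
#' @param annotation \code{GRanges} annotation (e.g. nucleosome-depleted
#'   regions).
#' @param genome \code{DNAStringSet}.
#' @param mappable optional mappability \code{GRanges}; default all
#'   mappable.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list with \code{ratio}, \code{p}, \code{nPerm} and
#'   \code{nullRatios}.
#' @export
annotationEnrichment <- function(regions, annotation, genome,
                                 mappable = NULL, nPerm = 1000L,
                                 seed = 1L) {
    set.seed(seed)
    space <- .mappableSpace(genome, mappable)
    ann <- GenomicRanges::intersect(
        GenomicRanges::reduce(annotation, ignore.strand = TRUE), space,
        ignore.strand = TRUE)
    totalMappable <- sum(as.numeric(BiocGenerics::width(space)))
    annFrac <- .overlapBp(ann, space) / totalMappable
    if (annFrac <= 0) stop("annotation has no mappable overlap")

    regionRatio <- function(gr) {
        inside <- .overlapBp(gr, space)
        if (inside == 0) return(NA_real_)
        (.overlapBp(gr, ann) / inside) / annFrac
    }
    observed <- regionRatio(regions)

    ## length-preserving uniform placement within mappable intervals; an
    ## interval is chosen with probability proportional to the number of
    ## start positions that fit the region. The null loop runs on plain
    ## numeric interval arithmetic against the per-chromosome annotation.
    spaceW <- BiocGenerics::width(space)
    spaceChr <- as.character(GenomicRanges::seqnames(space))
    spaceStart <- BiocGenerics::start(space)
    regW <- BiocGenerics::width(regions)
    if (any(regW > max(spaceW)))
        stop("a region is longer than the largest mappable interval")
    annByChr <- lapply(split(seq_along(ann),
                             as.character(GenomicRanges::seqnames(ann))),
                       function(i) cbind(s = BiocGenerics::start(ann)[i],
                                         e = BiocGenerics::end(ann)[i]))
    annOverlap <- function(ch, s, e) {
        a <- annByChr[[ch]]
        if (is.null(a)) return(0)
        sum(pmax(0, pmin(e, a[, "e"]) - pmax(s, a[, "s"]) + 1))
    }
    nullRatios <- vapply(seq_len(nPerm), function(i) {
        inAnn <- 0
        for (L in regW) {
            fit <- pmax(spaceW - L + 1L, 0L)
            j <- sample.int(length(spaceW), 1, prob = fit)
            s <- spaceStart[j] + sample.int(fit[j], 1) - 1L
            inAnn <- inAnn + annOverlap(spaceChr[j], s, s + L - 1L)
        }
        (inAnn / sum(regW)) / annFrac
    }, numeric(1))
    p <- (1 + sum(nullRatios >= observed, na.rm = TRUE)) / (1 + nPerm)
    list(ratio = observed, p = p, nPerm = as.integer(nPerm),
         nullRatios = nullRatios)
}
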