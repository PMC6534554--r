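## One-ended (replication-associated) DSB detection from Watson/Crick read
## imbalance. A two-ended break labels both strands around its position; a
## broken replication fork exposes a single double-strand end and labels
## only one strand, so windows with significant single-strand excess mark
## one-ended break regions.

#' Per-window Watson/Crick read counts
#'
#' Tiles each chromosome with non-overlapping windows (default 500 nt) and
#' counts read 5' ends per strand with a half-open rule, so boundary reads
#' are never double-counted.
#'
#' @param reads stranded \code{GRanges}.
#' @param genome \code{DNAStringSet}.
#' @param window tile width in nt.
#' @param dropEmpty drop windows with no reads at all.
#' @return \code{GRanges} of tiles with metadata columns \code{W} and
#'   \code{C}.
#' @export
windowStrandCounts <- function(reads, genome, window = 500L,
                               dropEmpty = FALSE) {
    lens <- genomeLengths(genome)
    p5 <- read5p0(reads)
    chr <- as.character(GenomicRanges::seqnames(reads))
    str <- as.character(GenomicRanges::strand(reads))
    if (any(str == "*")) stop("all reads must carry a strand")
    out <- vector("list", length(lens))
    for (i in seq_along(lens)) {
        ch <- names(lens)[i]
        nwin <- ceiling(lens[ch] / window)
        if (nwin == 0L) next
        sel <- chr == ch
        bin <- function(s) {
            x <- p5[sel & str == s] %/% window + 1L
            tabulate(x, nbins = nwin)
        }
        gr <- GenomicRanges::GRanges(
            seqnames = ch,
            ranges = IRanges::IRanges(
                start = (seq_len(nwin) - 1L) * window + 1L,
                end = pmin(seq_len(nwin) * window, lens[ch])),
            seqinfo = .genomeSeqinfo(genome))
        mcols(gr)$W <- bin("+")
        mcols(gr)$C <- bin("-")
        out[[i]] <- gr
    }
    gr <- do.call(c, out[!vapply(out, is.null, logical(1))])
    if (dropEmpty) gr <- gr[gr$W + gr$C > 0]
    gr
}

#' Hypergeometric test for one-ended break windows
#'
#' For each window, tests whether the Watson (and, separately, the Crick)
#' read count is larger than expected when drawing \code{W + C} reads from
#' the genome-wide strand composition (hypergeometric null). Both one-sided
#' p-values are Bonferroni-corrected over windows times two tests, and a
#' window is called one-ended when its corrected p-value falls below
#' \code{pThreshold}.
#'
#' @param windows \code{GRanges} from [windowStrandCounts()].
#' @param pThreshold threshold on the corrected p-value (default 1e-10).
#' @param totalsW,totalsC genome-wide strand totals; taken from
#'   \code{windows} when missing.
#' @param correctFirst apply the threshold after Bonferroni correction
#'   (default) or to raw p-values.
#' @return the windows with added metadata \code{pValue},
#'   \code{correctedP} and \code{call} (\code{"watson_one_ended"},
#'   \code{"crick_one_ended"} or \code{"balanced"}).
#' @export
oneEndedTest <- function(windows, pThreshold = 1e-10,
                         totalsW = NULL, totalsC = NULL,
                         correctFirst = TRUE) {
    W <- windows$W
    C <- windows$C
    if (is.null(totalsW)) totalsW <- sum(W)
    if (is.null(totalsC)) totalsC <- sum(C)
    if (totalsW + totalsC <= 0) stop("no reads in windows")
    n <- W + C
    pW <- stats::phyper(W - 1, totalsW, totalsC, n, lower.tail = FALSE)
    pC <- stats::phyper(C - 1, totalsC, totalsW, n, lower.tail = FALSE)
    p <- pmin(pW, pC)
    m <- 2 * length(W)  # windows x two one-sided tests
    corrected <- pmin(p * m, 1)
    eff <- if (correctFirst) corrected else p
    call <- rep("balanced", length(W))
    sig <- eff < pThreshold & n > 0
    call[sig & pW <= pC] <- "watson_one_ended"
    call[sig & pC < pW] <- "crick_one_ended"
    mcols(windows)$pValue <- p
    mcols(windows)$correctedP <- corrected
    mcols(windows)$call <- call
    windows
}

#' Quantify one-ended DSBs per cell
#'
#' Adjacent significant windows of the same polarity are merged (one broken
#' fork can span window boundaries), then the strand-read difference
#' \code{|W - C|} in each merged region is converted to breaks per cell by
#' the sample's spike-in coefficient. Optionally restricted to regions
#' overlapping an annotation (e.g. +/- 10 kb around replication origins).
#'
#' @param windows tested windows from [oneEndedTest()].
#' @param alpha labeled reads per DSB from the same sample's spike-in.
#' @param annotation optional \code{GRanges} restriction.
#' @return list with \code{total} (one-ended DSBs per cell),
#'   \code{regions} (merged \code{GRanges} with W, C and per-region
#'   breaks), and \code{inAnnotation} (total within the annotation, when
#'   given).
#' @export
quantifyOneEnded <- function(windows, alpha, annotation = NULL) {
    if (alpha <= 0) stop("alpha must be positive")
    sig <- windows[windows$call != "balanced"]
    if (!length(sig))
        return(list(total = 0, regions = sig, inAnnotation = if
            (is.null(annotation)) NULL else 0))
    merged <- list()
    for (pol in unique(sig$call)) {
        sub <- sig[sig$call == pol]
        red <- GenomicRanges::reduce(sub, min.gapwidth = 1L)
        hits <- GenomicRanges::findOverlaps(sub, red)
        Wm <- tapply(sub$W[S4Vectors::queryHits(hits)],
                     S4Vectors::subjectHits(hits), sum)
        Cm <- tapply(sub$C[S4Vectors::queryHits(hits)],
                     S4Vectors::subjectHits(hits), sum)
        mcols(red)$W <- as.integer(Wm)
        mcols(red)$C <- as.integer(Cm)
        mcols(red)$call <- pol
        merged[[pol]] <- red
    }
    regions <- do.call(c, unname(merged))
    mcols(regions)$breaksPerCell <- abs(regions$W - regions$C) / alpha
    total <- sum(regions$breaksPerCell)
    inAnn <- NULL
    if (!is.null(annotation)) {
        ov <- IRanges::overlapsAny(regions, annotation,
                                   ignore.strand = TRUE)
        inAnn <- sum(regions$breaksPerCell[ov])
    }
    list(total = total, regions = BiocGenerics::sort(regions),
         inAnnotation = inAnn)
}
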