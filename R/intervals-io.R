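.assertWithinGenome <- function(gr, genome, what = "interval") {
    lens <- genomeLengths(genome)
    chr <- as.character(GenomicRanges::seqnames(gr))
    bad <- !(chr %in% names(lens)) |
        BiocGenerics::start(gr) < 1L |
        BiocGenerics::end(gr) > lens[chr]
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
        i <- which(bad)[1]
        stop(sprintf("%s %d (%s:%d-%d) outside genome bounds",
                     what, i, chr[i], BiocGenerics::start(gr)[i],
                     BiocGenerics::end(gr)[i]))
    }
    invisible(gr)
}

#' Read mapped reads or paired-end fragments
#'
#' BED input is parsed as 0-based half-open and converted to the 1-based
#' closed \code{GRanges} frame; SAM/BAM is converted to the same frame. With
#' \code{paired = TRUE}, properly paired alignments are collapsed to the
#' outer span of the pair (the sequenced gDNA fragment). Out-of-bounds
#' records raise an error (never silent clamping) when a genome is supplied.
#'
#' @param path input file (BED6, SAM or BAM).
#' @param format \code{"auto"} (by extension), \code{"bed"}, \code{"sam"} or
#'   \code{"bam"}.
#' @param genome optional \code{DNAStringSet} used for bounds checking.
#' @param paired collapse pairs to fragments (SAM/BAM only).
#' @return \code{GRanges}; reads carry strand, fragments are unstranded.
#' @export
readIntervals <- function(path, format = c("auto", "bed", "sam", "bam"),
                          genome = NULL, paired = FALSE) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, bed = "bed", sam = "sam", bam = "bam",
                         stop("cannot guess format from extension: ", ext))
    }
    gr <- if (format == "bed") .readBed(path) else
        .readSamBam(path, isSam = (format == "sam"), paired = paired)
    if (!is.null(genome)) .assertWithinGenome(gr, genome, "record")
    gr
}

.readBed <- function(path) {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e)
                       stop("malformed BED in ", path, ": ",
                            conditionMessage(e)))
    gr <- methods::as(gr, "GRanges")
    if (any(BiocGenerics::width(gr) < 1L)) {
        i <- which(BiocGenerics::width(gr) < 1L)[1]
        stop(sprintf("BED record %d has start >= end (zero-width interval)", i))
    }
    gr
}

.readSamBam <- function(path, isSam, paired) {
    bam <- path
    if (isSam)
        bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                indexDestination = FALSE)
    what <- c("rname", "pos", "qwidth", "strand", "flag", "isize", "seq")
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
    p <- Rsamtools::ScanBamParam(what = what, flag = flag)
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    keep <- !is.na(x$pos)
    if (paired) {
        ## leftmost mate of each proper pair carries a positive TLEN spanning
        ## the whole fragment
        sel <- keep & !is.na(x$isize) & x$isize > 0 &
            bitwAnd(x$flag, 0x1) > 0 & bitwAnd(x$flag, 0x2) > 0
        if (!any(sel)) stop("no properly paired records in ", path)
        GenomicRanges::GRanges(
            seqnames = as.character(x$rname[sel]),
            ranges = IRanges::IRanges(start = x$pos[sel],
                                      width = x$isize[sel]))
    } else {
        sel <- keep
        gr <- GenomicRanges::GRanges(
            seqnames = as.character(x$rname[sel]),
            ranges = IRanges::IRanges(start = x$pos[sel],
                                      width = x$qwidth[sel]),
            strand = x$strand[sel])
        mcols(gr)$seq <- as.character(x$seq[sel])
        gr
    }
}

#' Write a per-window value track as bedGraph
#'
#' Standard 4-column bedGraph with values printed to 6 decimals, so a write
#' followed by [readBedGraph()] reproduces the values exactly at that
#' precision. Windows must be sorted; fractional and zero values are fine.
#'
#' @param track \code{GRanges} with a numeric \code{score} column.
#' @param path output path.
#' @param trackHeader write a \code{track type=bedGraph} header line.
#' @return the path, invisibly.
#' @export
writeBedGraph <- function(track, path, trackHeader = FALSE) {
    if (length(track)) {
        o <- order(match(as.character(GenomicRanges::seqnames(track)),
                         GenomeInfoDb::seqlevels(track)),
                   BiocGenerics::start(track))
        if (!identical(o, seq_along(track)))
            stop("track windows must be sorted by (chrom, start)")
        if (is.null(track$score)) stop("track needs a 'score' column")
        if (any(track$score < 0)) stop("bedGraph values must be >= 0")
    }
    con <- file(path, "w")
    on.exit(close(con))
    if (trackHeader) writeLines("track type=bedGraph", con)
    if (length(track))
        writeLines(sprintf("%s\t%d\t%d\t%.6f",
                           as.character(GenomicRanges::seqnames(track)),
                           BiocGenerics::start(track) - 1L,
                           BiocGenerics::end(track),
                           track$score), con)
    invisible(path)
}

#' Read a bedGraph track
#' @param path bedGraph file.
#' @return \code{GRanges} with a \code{score} column.
#' @export
readBedGraph <- function(path) {
    methods::as(rtracklayer::import(path, format = "bedGraph"), "GRanges")
}
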