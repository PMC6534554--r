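#' Read a genome from FASTA
#'
#' Reads a multi-record FASTA file into a \code{DNAStringSet}, upper-casing
#' sequences and enforcing the strict genome alphabet A/C/G/T/N. IUPAC
#' ambiguity codes and anything else (e.g. RNA \code{U}) are rejected rather
#' than silently converted.
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}; chromosome names must be unique.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGT"), fa)
#' readGenomeFasta(fa)
#' @export
readGenomeFasta <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    raw <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e)
                        stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e)))
    seqs <- toupper(as.character(raw))
    names(seqs) <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(names(seqs)))
        stop("duplicate chromosome names in ", path)
    ok <- grepl("^[ACGTN]*$", seqs)
    if (!all(ok)) {
        badchr <- names(seqs)[!ok][1]
        badch <- setdiff(strsplit(seqs[!ok][1], "")[[1]], c("A","C","G","T","N"))
        stop("sequence for ", badchr,
             " contains characters outside A/C/G/T/N: ",
             paste(utils::head(badch, 5), collapse = ","))
    }
    Biostrings::DNAStringSet(seqs)
}

#' Chromosome lengths of a genome
#' @param genome a \code{DNAStringSet}.
#' @return named integer vector of lengths.
#' @export
genomeLengths <- function(genome) {
    stats::setNames(Biostrings::width(genome), names(genome))
}

.genomeSeqinfo <- function(genome) {
    GenomeInfoDb::Seqinfo(seqnames = names(genome),
                          seqlengths = genomeLengths(genome))
}

#' 0-based cut positions of a cut-site GRanges
#'
#' Cut sites are stored as width-1 \code{GRanges} whose start is the 1-based
#' coordinate of the first base 3' of the top-strand scission; this helper
#' returns the equivalent 0-based cut coordinate (the boundary between base
#' \code{cutPos0 - 1} and base \code{cutPos0}).
#'
#' @param sites cut-site \code{GRanges} from [findCutSites()].
#' @return integer vector of 0-based cut positions.
#' @export
cutPos0 <- function(sites) {
    BiocGenerics::start(sites) - 1L
}

#' Find enzyme cutting sites in a genome
#'
#' Scans both strands for the recognition motif (IUPAC codes honoured) and
#' reports one site per distinct top-strand cut coordinate. Palindromic
#' motifs are reported once per position; overlapping occurrences each yield
#' a site, and duplicate cut positions are merged. Sites whose cut falls on
#' a chromosome boundary are dropped.
#'
#' @param genome \code{DNAStringSet}.
#' @param enz an [EnzymeSpec-class].
#' @param vicinity half-width in bp of the counting vicinity stored with each
#'   site (default 3, the empirically determined window around canonical
#'   cutting sites).
#' @return \code{GRanges} of width-1 sites sorted by (chrom, cut position),
#'   with metadata columns \code{enzyme}, \code{motifStrand},
#'   \code{vicinity}.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AAGCGGCCGCTT"))
#' findCutSites(g, builtinEnzymes()$NotI)  # cut after GC^GGCCGC
#' @export
findCutSites <- function(genome, enz, vicinity = 3L) {
    stopifnot(is(enz, "EnzymeSpec"))
    validObject(enz)
    if (vicinity < 0) stop("vicinity must be >= 0")
    motif <- Biostrings::DNAString(enz@recognition)
    rcmot <- Biostrings::reverseComplement(motif)
    L <- length(motif)
    palindromic <- as.character(motif) == as.character(rcmot)
    lens <- genomeLengths(genome)

    hitTable <- function(pattern, cutFromStart) {
        m <- Biostrings::vmatchPattern(pattern, genome, fixed = FALSE)
        do.call(rbind, lapply(seq_along(m), function(i) {
            st <- BiocGenerics::start(m[[i]])
            if (!length(st)) return(NULL)
            data.frame(chrom = names(genome)[i],
                       cut0 = (st - 1L) + cutFromStart,
                       stringsAsFactors = FALSE)
        }))
    }

    plus <- hitTable(motif, enz@cutOffsetTop)
    if (!is.null(plus) && nrow(plus)) plus$motifStrand <- "+"
    minus <- NULL
    if (!palindromic) {
        minus <- hitTable(rcmot, L - enz@cutOffsetBottom)
        if (!is.null(minus) && nrow(minus)) minus$motifStrand <- "-"
    }
    hits <- rbind(plus, minus)
    if (is.null(hits) || !nrow(hits)) {
        gr <- GenomicRanges::GRanges(seqinfo = .genomeSeqinfo(genome))
        mcols(gr)$enzyme <- character()
        mcols(gr)$motifStrand <- character()
        mcols(gr)$vicinity <- integer()
        return(gr)
    }
    ## drop cuts on chromosome boundaries, dedupe, sort
    hits <- hits[hits$cut0 > 0L & hits$cut0 < lens[hits$chrom], , drop = FALSE]
    hits <- hits[!duplicated(hits[c("chrom", "cut0")]), , drop = FALSE]
    hits <- hits[order(match(hits$chrom, names(genome)), hits$cut0), ,
                 drop = FALSE]
    gr <- GenomicRanges::GRanges(
        seqnames = hits$chrom,
        ranges = IRanges::IRanges(start = hits$cut0 + 1L, width = 1L),
        strand = hits$motifStrand,
        seqinfo = .genomeSeqinfo(genome))
    mcols(gr)$enzyme <- enz@name
    mcols(gr)$motifStrand <- hits$motifStrand
    mcols(gr)$vicinity <- as.integer(vicinity)
    gr
}

#' In-silico digestion statistics
#'
#' Counts recognition sites for each enzyme and reports site density per Mb
#' and the median distance between consecutive cuts on the same chromosome.
#' The table is sorted by decreasing site density, the natural ordering when
#' choosing a spike-in enzyme for a genome.
#'
#' @param genome \code{DNAStringSet}.
#' @param enzymes list of [EnzymeSpec-class] objects (or a single one).
#' @return data.frame with columns \code{enzyme}, \code{n_sites},
#'   \code{sites_per_mb}, \code{median_inter_site_distance}.
#' @export
digestionStats <- function(genome, enzymes) {
    total <- sum(as.numeric(genomeLengths(genome)))
    if (length(genome) == 0L || total == 0)
        stop("genome is empty")
    if (is(enzymes, "EnzymeSpec")) enzymes <- list(enzymes)
    rows <- lapply(enzymes, function(e) {
        sites <- findCutSites(genome, e)
        n <- length(sites)
        med <- NA_real_
        if (n >= 2L) {
            gaps <- unlist(lapply(split(cutPos0(sites),
                                        as.character(GenomicRanges::seqnames(sites))),
                                  function(x) if (length(x) >= 2L) diff(sort(x))))
            if (length(gaps)) med <- stats::median(gaps)
        }
        data.frame(enzyme = e@name, n_sites = n,
                   sites_per_mb = n / total * 1e6,
                   median_inter_site_distance = med,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$sites_per_mb), , drop = FALSE]
    rownames(out) <- NULL
    out
}
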