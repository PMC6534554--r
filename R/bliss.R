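## UMI-based break counting (BLISS-style), used as a cross-method
## comparison against spike-in quantification. Unlike the spike-in
## estimator, the UMI total scales with sequencing depth, which is the
## central instability this package's depth-invariance tests demonstrate.

#' Read a UMI table
#'
#' Tab-separated table with columns \code{chrom}, \code{pos} (0-based first
#' nucleotide of the mapped read), \code{umi}, \code{barcode}.
#'
#' @param path TSV path (header optional; columns in the above order when
#'   absent).
#' @return data.frame.
#' @export
readUmiTable <- function(path) {
    first <- readLines(path, n = 1)
    hasHeader <- grepl("chrom", first, fixed = TRUE)
    df <- utils::read.table(path, sep = "\t", header = hasHeader,
                            stringsAsFactors = FALSE,
                            col.names = if (hasHeader) NULL else
                                c("chrom", "pos", "umi", "barcode"))
    need <- c("chrom", "pos", "umi", "barcode")
    if (!all(need %in% names(df)))
        stop("UMI table needs columns: ", paste(need, collapse = ", "))
    df
}

#' Deduplicate UMI records
#'
#' Exact-match deduplication on (chrom, pos, umi) after optional barcode
#' filtering; no edit-distance collapsing. One record per unique molecular
#' event is retained.
#'
#' @param records data.frame with chrom, pos, umi, barcode.
#' @param barcode expected sample barcode; records with other barcodes are
#'   dropped. \code{NULL} keeps all.
#' @param umiLength expected UMI length; records violating it are dropped.
#' @return data.frame of unique records.
#' @export
dedupUmis <- function(records, barcode = NULL, umiLength = NULL) {
    if (!is.null(barcode))
        records <- records[records$barcode == barcode, , drop = FALSE]
    if (!is.null(umiLength))
        records <- records[nchar(records$umi) == umiLength, , drop = FALSE]
    records[!duplicated(records[c("chrom", "pos", "umi")]), , drop = FALSE]
}

#' Count unique UMIs near cutting sites
#'
#' Counts deduplicated UMI records whose position lies within
#' \code{+/- halfWindow} of a site. Sites closer than \code{mergeDistance}
#' are merged into a single counting interval so no UMI is double-counted;
#' sites on excluded chromosomes are dropped.
#'
#' @param unique deduplicated records from [dedupUmis()].
#' @param sites cut-site \code{GRanges} (sorted).
#' @param halfWindow interval half-width in bp (default 100).
#' @param mergeDistance merge sites closer than this (default 200 bp).
#' @param excludeChroms chromosomes to drop (default \code{"chrY"}).
#' @return number of unique UMIs attributable to the sites.
#' @export
countUmisNearSites <- function(unique, sites, halfWindow = 100L,
                               mergeDistance = 200L,
                               excludeChroms = "chrY") {
    sites <- sites[!as.character(GenomicRanges::seqnames(sites)) %in%
                       excludeChroms]
    if (!length(sites) || !nrow(unique)) return(0L)
    c0 <- cutPos0(sites)
    ## intervals in 0-based position space; sites closer than mergeDistance
    ## have touching/overlapping intervals and are merged by reduce()
    iv <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(sites),
        IRanges::IRanges(start = pmax(c0 - halfWindow, 0L) + 1L,
                         end = c0 + halfWindow + 1L))
    iv <- GenomicRanges::reduce(iv, min.gapwidth = 0L)
    pts <- GenomicRanges::GRanges(unique$chrom,
                                  IRanges::IRanges(unique$pos + 1L,
                                                   width = 1L))
    sum(IRanges::overlapsAny(pts, iv))
}

#' UMI-based breaks per cell with Poisson SD
#'
#' \code{estimate = nUmi / nCell}; the SD treats both counts as Poisson:
#' \deqn{\frac12\Big(\frac{N_{UMI}+\sqrt{N_{UMI}}}{N_{cell}-\sqrt{N_{cell}}}
#'  - \frac{N_{UMI}-\sqrt{N_{UMI}}}{N_{cell}+\sqrt{N_{cell}}}\Big)}
#'
#' @param nUmi unique UMI count near sites.
#' @param nCell number of cells in the sample.
#' @return list with \code{estimate} and \code{sd}.
#' @examples
#' blissDsbsPerCell(96, 1200)   # 0.08 DSBs per cell
#' blissDsbsPerCell(100, 10000) # SD 0.0011
#' @export
blissDsbsPerCell <- function(nUmi, nCell) {
    if (nCell < 1) stop("nCell must be >= 1")
    if (nCell - sqrt(nCell) <= 0)
        stop("nCell too small for the Poisson approximation")
    if (nUmi < 0) stop("nUmi must be >= 0")
    est <- nUmi / nCell
    sd <- if (nUmi == 0) 0 else
        ((nUmi + sqrt(nUmi)) / (nCell - sqrt(nCell)) -
         (nUmi - sqrt(nUmi)) / (nCell + sqrt(nCell))) / 2
    list(estimate = est, sd = sd)
}
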