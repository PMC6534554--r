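#' Estimate spike-in cutting efficiency from a gDNA library
#'
#' Convenience chain: classify fragments at every site, estimate the
#' background efficiency from random windows, and pool across sites.
#'
#' @param fragments gDNA fragment \code{GRanges}.
#' @param genome \code{DNAStringSet}.
#' @param sites cut-site \code{GRanges}.
#' @param w vicinity half-width (default 3).
#' @param minReads per-site depth filter (default 100).
#' @param nWindows background windows (default 1500).
#' @param seed seed for the background window sampler.
#' @return an [EfficiencyEstimate-class].
#' @export
estimateEfficiency <- function(fragments, genome, sites, w = 3L,
                               minReads = 100, nWindows = 1500L,
                               seed = 1L) {
    counts <- countsAtSites(fragments, sites, w = w)
    bg <- estimateBackground(fragments, genome, sites = sites, w = w,
                             nWindows = nWindows, seed = seed)
    pooledEfficiency(counts, fBg = bg, minReads = minReads)
}

#' Full spike-in quantification of a labeled sample
#'
#' Runs the whole chain on one sample: count labeled reads at the spike-in
#' sites, filter the remaining reads down to studied-break reads, convert
#' via the spike-in coefficient, and attach the per-site (or propagated)
#' SD.
#'
#' @param reads labeled read \code{GRanges} (metadata \code{seq} needed for
#'   telomere filtering).
#' @param efficiency an [EfficiencyEstimate-class] for the spike-in enzyme.
#' @param sites cut-site \code{GRanges}.
#' @param p proportion of digested cells.
#' @param w vicinity half-width for read-site assignment.
#' @param telomere apply the telomeric-read filter.
#' @param masks optional mask \code{GRanges} (rDNA etc.).
#' @return list with \code{quant} (a [QuantResult-class]), \code{audit}
#'   (filter audit table) and \code{perSiteB} (per-site break estimates).
#' @export
quantifySample <- function(reads, efficiency, sites, p = 1, w = 3L,
                           telomere = FALSE, masks = NULL) {
    rCut <- countReadsAtSites(reads, sites, w = w)
    perSiteR <- countReadsAtSites(reads, sites, w = w, perSite = TRUE)
    filt <- filterStudiedReads(reads, sites = sites, w = w,
                               telomere = telomere, masks = masks)
    bCut <- spikeInBreaks(efficiency, length(sites), p = p)
    sdInfo <- perSiteSD(perSiteR, efficiency@perSite$fSite, p = p,
                        rStudied = filt$rStudied, efficiency = efficiency)
    quant <- quantifyDSBs(filt$rStudied, rCut, bCut,
                          sdB = sdInfo$sd, sdMethod = sdInfo$method)
    list(quant = quant, audit = filt$audit, perSiteB = sdInfo$perSiteB)
}
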