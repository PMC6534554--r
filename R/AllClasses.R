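#' @import methods
#' @importFrom S4Vectors metadata mcols mcols<-
NULL

#' Restriction enzyme specification
#'
#' Describes a restriction (or homing) endonuclease by its recognition motif
#' and the positions of the two strand scissions. Offsets are measured in bp
#' from the 5' end of the top-strand motif: the top strand is cut between
#' motif positions \code{cutOffsetTop - 1} and \code{cutOffsetTop} (0-based),
#' and likewise for the bottom strand, both expressed in top-strand
#' coordinates. Equal offsets give blunt ends; a bottom offset larger than
#' the top offset gives a 5' overhang, smaller gives a 3' overhang.
#'
#' @slot name enzyme name.
#' @slot recognition recognition motif (IUPAC alphabet allowed).
#' @slot cutOffsetTop integer, top-strand cut offset within the motif.
#' @slot cutOffsetBottom integer, bottom-strand cut offset (top-strand frame).
#' @slot endType one of \code{"blunt"}, \code{"5overhang"}, \code{"3overhang"}.
#'
#' @examples
#' enzyme("NotI", "GCGGCCGC", 2L, 6L, "5overhang")
#' @export
setClass("EnzymeSpec",
    representation(
        name = "character",
        recognition = "character",
        cutOffsetTop = "integer",
        cutOffsetBottom = "integer",
        endType = "character"
    )
)

setValidity("EnzymeSpec", function(object) {
    msg <- character()
    if (nchar(object@recognition) < 4L)
        msg <- c(msg, "recognition motif must be at least 4 nt")
    bad <- setdiff(strsplit(object@recognition, "")[[1]],
                   strsplit("ACGTRYSWKMBDHVN", "")[[1]])
    if (length(bad))
        msg <- c(msg, paste0("non-IUPAC characters in motif: ",
                             paste(bad, collapse = ",")))
    if (!object@endType %in% c("blunt", "5overhang", "3overhang"))
        msg <- c(msg, "endType must be blunt, 5overhang or 3overhang")
    dt <- object@cutOffsetBottom - object@cutOffsetTop
    expect <- if (dt == 0L) "blunt" else if (dt > 0L) "5overhang" else "3overhang"
    if (object@endType %in% c("blunt", "5overhang", "3overhang") &&
        object@endType != expect)
        msg <- c(msg, sprintf(
            "endType '%s' inconsistent with cut offsets (implies '%s')",
            object@endType, expect))
    if (length(msg)) msg else TRUE
})

#' Background cutting-efficiency estimate
#'
#' Result of sampling random genomic windows away from true cut sites and
#' applying the cut/uncut fragment classifier to a pseudo-site at each window
#' center. \code{fBg} is the mean apparent efficiency over windows and
#' \code{sigmaBg} its per-window standard deviation (a deliberately
#' conservative spread, not a standard error).
#'
#' @slot fBg mean background efficiency.
#' @slot sigmaBg SD of per-window background efficiencies.
#' @slot nWindows number of windows sampled.
#' @slot windowSize window size in bp (vicinity span).
#' @slot seed RNG seed used.
#' @export
setClass("BackgroundEstimate",
    representation(
        fBg = "numeric",
        sigmaBg = "numeric",
        nWindows = "integer",
        windowSize = "integer",
        seed = "integer"
    )
)

setValidity("BackgroundEstimate", function(object) {
    if (object@fBg < 0 || object@fBg > 1)
        return("fBg must be in [0, 1]")
    TRUE
})

#' Cutting-efficiency estimate with decomposed uncertainty
#'
#' @slot fCut pooled cutting efficiency after background subtraction.
#' @slot sigmaPoisson Poisson (counting) SD component.
#' @slot sigmaBg background SD component.
#' @slot sigmaTotal combined SD, \code{sqrt(sigmaBg^2 + sigmaPoisson^2)}.
#' @slot perSite per-site data.frame: nCut, nUncut, fSite, pass, reason.
#' @slot nSitesUsed number of sites passing the pooling filters.
#' @export
setClass("EfficiencyEstimate",
    representation(
        fCut = "numeric",
        sigmaPoisson = "numeric",
        sigmaBg = "numeric",
        sigmaTotal = "numeric",
        perSite = "data.frame",
        nSitesUsed = "integer"
    )
)

setValidity("EfficiencyEstimate", function(object) {
    msg <- character()
    if (object@fCut < 0 || object@fCut > 1)
        msg <- c(msg, "fCut must lie in [0, 1] after clamping")
    st <- sqrt(object@sigmaBg^2 + object@sigmaPoisson^2)
    if (is.finite(st) && is.finite(object@sigmaTotal) &&
        abs(st - object@sigmaTotal) > 1e-8)
        msg <- c(msg, "sigmaTotal != sqrt(sigmaBg^2 + sigmaPoisson^2)")
    if (length(msg)) msg else TRUE
})

#' Spike-in calibrated quantification result
#'
#' Holds the full chain from spike-in breaks per cell (\code{bCut}) and
#' labeled reads at cut sites (\code{rCut}) through the reads-per-break
#' coefficient \code{alpha = rCut / bCut} to the studied break frequency
#' \code{bStudied = rStudied / alpha}.
#'
#' @slot bCut spike-in DSBs per cell.
#' @slot rCut labeled reads at enzyme cutting sites.
#' @slot alpha labeled reads per DSB.
#' @slot rStudied labeled reads attributed to studied DSBs (after filtering).
#' @slot bStudied studied DSBs per cell.
#' @slot sdB SD of bStudied.
#' @slot sdMethod \code{"per_site"} or \code{"propagated"} (or \code{"none"}).
#' @export
setClass("QuantResult",
    representation(
        bCut = "numeric",
        rCut = "numeric",
        alpha = "numeric",
        rStudied = "numeric",
        bStudied = "numeric",
        sdB = "numeric",
        sdMethod = "character"
    )
)

setValidity("QuantResult", function(object) {
    msg <- character()
    if (any(c(object@bCut, object@rCut, object@alpha,
              object@rStudied, object@bStudied) < 0, na.rm = TRUE))
        msg <- c(msg, "all quantities must be non-negative")
    if (is.finite(object@alpha) && object@bCut > 0 &&
        abs(object@alpha - object@rCut / object@bCut) >
            1e-8 * max(1, object@alpha))
        msg <- c(msg, "alpha != rCut / bCut")
    if (length(msg)) msg else TRUE
})

#' Planted break landscape for the read simulator
#'
#' Describes the classes of breaks the DSB-read simulator emits on top of the
#' enzyme spike-ins: two-ended breaks (reads on both strands around the
#' position), one-ended replication-type breaks (reads on a single strand,
#' set by \code{polarity}), a uniform per-bp background, and a fraction of
#' telomere-motif reads.
#'
#' @slot twoEnded data.frame(chrom, pos, freq) with per-cell frequencies.
#' @slot oneEnded data.frame(chrom, pos, freq, polarity) with polarity
#'   \code{"+"} (Watson reads only) or \code{"-"} (Crick reads only).
#' @slot uniformBackground DSBs per cell per bp.
#' @slot telomereReadFraction fraction of emitted reads that are
#'   telomere-motif reads.
#' @export
setClass("BreakLandscape",
    representation(
        twoEnded = "data.frame",
        oneEnded = "data.frame",
        uniformBackground = "numeric",
        telomereReadFraction = "numeric"
    )
)

setValidity("BreakLandscape", function(object) {
    msg <- character()
    need2 <- c("chrom", "pos", "freq")
    need1 <- c("chrom", "pos", "freq", "polarity")
    if (nrow(object@twoEnded) && !all(need2 %in% names(object@twoEnded)))
        msg <- c(msg, "twoEnded needs columns chrom, pos, freq")
    if (nrow(object@oneEnded)) {
        if (!all(need1 %in% names(object@oneEnded)))
            msg <- c(msg, "oneEnded needs columns chrom, pos, freq, polarity")
        else if (!all(object@oneEnded$polarity %in% c("+", "-")))
            msg <- c(msg, "oneEnded polarity must be '+' or '-'")
    }
    freqs <- c(object@twoEnded$freq, object@oneEnded$freq)
    if (length(freqs) && any(freqs < 0 | freqs > 1))
        msg <- c(msg, "per-site per-cell frequencies must lie in [0, 1]")
    if (object@uniformBackground < 0)
        msg <- c(msg, "uniformBackground must be >= 0")
    if (object@telomereReadFraction < 0 || object@telomereReadFraction >= 1)
        msg <- c(msg, "telomereReadFraction must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "EnzymeSpec", function(object) {
    cat(sprintf("EnzymeSpec %s: %s (top cut %d, bottom cut %d, %s)\n",
                object@name, object@recognition, object@cutOffsetTop,
                object@cutOffsetBottom, object@endType))
})

setMethod("show", "BackgroundEstimate", function(object) {
    cat(sprintf(
        "BackgroundEstimate: fBg = %.5f (sigma %.5f) from %d windows of %d bp\n",
        object@fBg, object@sigmaBg, object@nWindows, object@windowSize))
})

setMethod("show", "EfficiencyEstimate", function(object) {
    cat(sprintf("EfficiencyEstimate: fCut = %.4f +/- %.4f\n",
                object@fCut, object@sigmaTotal))
    cat(sprintf("  sigmaPoisson = %.5f, sigmaBg = %.5f\n",
                object@sigmaPoisson, object@sigmaBg))
    cat(sprintf("  %d of %d sites used\n",
                object@nSitesUsed, nrow(object@perSite)))
})

setMethod("show", "QuantResult", function(object) {
    cat("QuantResult:\n")
    cat(sprintf("  spike-in: bCut = %.4g DSB/cell, rCut = %g reads\n",
                object@bCut, object@rCut))
    cat(sprintf("  alpha    = %.4g reads per DSB\n", object@alpha))
    cat(sprintf("  studied : rStudied = %g reads -> bStudied = %.4g DSB/cell",
                object@rStudied, object@bStudied))
    if (is.finite(object@sdB))
        cat(sprintf(" +/- %.3g (%s)", object@sdB, object@sdMethod))
    cat("\n")
})

setMethod("show", "BreakLandscape", function(object) {
    cat(sprintf(
        "BreakLandscape: %d two-ended, %d one-ended, background %g DSB/cell/bp, telomere fraction %g\n",
        nrow(object@twoEnded), nrow(object@oneEnded),
        object@uniformBackground, object@telomereReadFraction))
})

## ---- accessors --------------------------------------------------------------

#' @describeIn EfficiencyEstimate-accessors pooled cutting efficiency
#' @export
fCut <- function(x) {
    stopifnot(is(x, "EfficiencyEstimate"))
    x@fCut
}

#' Accessors for estimate objects
#'
#' Small accessor family for the quantification S4 classes, so user code
#' never touches slots directly.
#'
#' @param x an \code{EfficiencyEstimate} or \code{QuantResult}.
#' @return numeric scalar (or data.frame for \code{perSiteTable}).
#' @name EfficiencyEstimate-accessors
NULL

#' @describeIn EfficiencyEstimate-accessors combined SD of fCut
#' @export
sigmaTotal <- function(x) {
    stopifnot(is(x, "EfficiencyEstimate"))
    x@sigmaTotal
}

#' @describeIn EfficiencyEstimate-accessors per-site count/efficiency table
#' @export
perSiteTable <- function(x) {
    stopifnot(is(x, "EfficiencyEstimate"))
    x@perSite
}

#' @describeIn EfficiencyEstimate-accessors reads-per-DSB coefficient
#' @export
alphaCoef <- function(x) {
    stopifnot(is(x, "QuantResult"))
    x@alpha
}

#' @describeIn EfficiencyEstimate-accessors studied DSBs per cell
#' @export
bStudied <- function(x) {
    stopifnot(is(x, "QuantResult"))
    x@bStudied
}

#' @describeIn EfficiencyEstimate-accessors SD of studied DSBs per cell
#' @export
sdBStudied <- function(x) {
    stopifnot(is(x, "QuantResult"))
    x@sdB
}
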