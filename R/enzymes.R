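#' Construct an enzyme specification
#'
#' @param name enzyme name.
#' @param recognition recognition motif, IUPAC codes allowed.
#' @param cutOffsetTop top-strand cut offset in bp from the motif 5' end.
#' @param cutOffsetBottom bottom-strand cut offset, in top-strand coordinates.
#' @param endType \code{"blunt"}, \code{"5overhang"} or \code{"3overhang"};
#'   inferred from the offsets when missing.
#' @return an [EnzymeSpec-class] object.
#' @examples
#' enzyme("BamHI", "GGATCC", 1, 5)
#' @export
enzyme <- function(name, recognition, cutOffsetTop, cutOffsetBottom,
                   endType = NULL) {
    recognition <- toupper(recognition)
    if (is.null(endType)) {
        dt <- cutOffsetBottom - cutOffsetTop
        endType <- if (dt == 0) "blunt" else if (dt > 0) "5overhang" else "3overhang"
    }
    new("EnzymeSpec", name = name, recognition = recognition,
        cutOffsetTop = as.integer(cutOffsetTop),
        cutOffsetBottom = as.integer(cutOffsetBottom),
        endType = endType)
}

#' Built-in enzyme definitions
#'
#' The enzymes commonly used to induce spike-in DSBs: NotI, SrfI, AsiSI and
#' BamHI for in vitro digestion and the homing endonuclease I-SceI for
#' in vivo single-site digestion.
#'
#' @return named list of [EnzymeSpec-class] objects.
#' @examples
#' builtinEnzymes()$NotI
#' @export
builtinEnzymes <- function() {
    list(
        NotI  = enzyme("NotI",  "GCGGCCGC", 2, 6),
        SrfI  = enzyme("SrfI",  "GCCCGGGC", 4, 4),
        AsiSI = enzyme("AsiSI", "GCGATCGC", 5, 3),
        BamHI = enzyme("BamHI", "GGATCC",   1, 5),
        ISceI = enzyme("I-SceI", "TAGGGATAACAGGGTAAT", 9, 5)
    )
}

#' Read enzyme definitions from a YAML config
#'
#' Each entry must provide \code{name}, \code{recognition},
#' \code{cut_offset_top}, \code{cut_offset_bottom} and optionally
#' \code{end_type}.
#'
#' @param path path to a YAML file with a list of enzyme entries.
#' @return named list of [EnzymeSpec-class] objects.
#' @export
readEnzymeConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$enzymes)) cfg <- cfg$enzymes
    out <- lapply(cfg, function(e) {
        need <- c("name", "recognition", "cut_offset_top", "cut_offset_bottom")
        miss <- setdiff(need, names(e))
        if (length(miss))
            stop("enzyme config entry missing fields: ",
                 paste(miss, collapse = ", "))
        enzyme(e$name, e$recognition, e$cut_offset_top, e$cut_offset_bottom,
               endType = e$end_type)
    })
    names(out) <- vapply(out, function(e) e@name, character(1))
    out
}
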