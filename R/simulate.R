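## Synthetic data with planted ground truth.
##
## The generators emulate the data classes the quantification pipeline
## consumes: gDNA fragment libraries around enzyme cut sites, break-labeled
## read sets (spike-ins, two-ended and one-ended studied breaks, uniform
## background, telomere-motif reads) and UMI-tagged read tables. Every
## generator takes a seed and is fully deterministic given it.

.randSeq <- function(n, gc) {
    sample(c("A", "T", "G", "C"), n, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

#' Construct a planted break landscape
#'
#' @param twoEnded data.frame(chrom, pos, freq); \code{pos} is the 0-based
#'   break position and \code{freq} the per-cell break frequency.
#' @param oneEnded data.frame(chrom, pos, freq, polarity); polarity \code{"+"}
#'   emits Watson-only reads, \code{"-"} Crick-only.
#' @param uniformBackground DSBs per cell per bp, spread uniformly.
#' @param telomereReadFraction fraction of emitted reads carrying the
#'   telomeric CAC-repeat sequence.
#' @return a [BreakLandscape-class].
#' @export
breakLandscape <- function(twoEnded = NULL, oneEnded = NULL,
                           uniformBackground = 0,
                           telomereReadFraction = 0) {
    empty2 <- data.frame(chrom = character(), pos = integer(),
                         freq = numeric())
    empty1 <- cbind(empty2, data.frame(polarity = character()))
    new("BreakLandscape",
        twoEnded = if (is.null(twoEnded)) empty2 else twoEnded,
        oneEnded = if (is.null(oneEnded)) empty1 else oneEnded,
        uniformBackground = uniformBackground,
        telomereReadFraction = telomereReadFraction)
}

#' Simulate a genome with planted enzyme recognition sites
#'
#' Generates random chromosome sequences at the requested GC content and
#' embeds exactly the requested number of motif occurrences per enzyme.
#' Accidental occurrences arising by chance are scrubbed by point mutation,
#' so an in-silico digestion recovers exactly the planted sites.
#'
#' @param lengths named integer vector of chromosome lengths (>= 10 kb
#'   recommended); unnamed vectors get chr1, chr2, ...
#' @param gcContent GC fraction of the random background (default 0.38,
#'   yeast-like).
#' @param embed list of \code{list(enzyme = EnzymeSpec, n = count)} entries.
#' @param minSeparation minimum bp between planted motifs (default 2000).
#' @param edgeMargin minimum bp between a planted motif and a chromosome end.
#' @param seed RNG seed.
#' @return list with \code{genome} (\code{DNAStringSet}) and \code{sites}
#'   (cut-site \code{GRanges} as from [findCutSites()], all enzymes
#'   combined).
#' @export
simulateGenome <- function(lengths, gcContent = 0.38, embed = list(),
                           minSeparation = 2000L, edgeMargin = 1000L,
                           seed = 1L) {
    set.seed(seed)
    if (is.null(names(lengths)))
        names(lengths) <- paste0("chr", seq_along(lengths))
    chroms <- lapply(lengths, .randSeq, gc = gcContent)

    planted <- data.frame(chrom = character(), start0 = integer(),
                          len = integer())
    for (item in embed) {
        enz <- item$enzyme
        n <- item$n
        if (n == 0L) next
        motif <- strsplit(enz@recognition, "")[[1]]
        if (any(!motif %in% c("A", "C", "G", "T")))
            stop("can only embed concrete (non-ambiguous) motifs")
        L <- length(motif)
        placed <- 0L
        tries <- 0L
        while (placed < n) {
            tries <- tries + 1L
            if (tries > 200L * n)
                stop("cannot place ", n, " motifs of ", enz@name,
                     " without overlap; genome too small")
            ch <- sample(names(lengths), 1, prob = lengths)
            if (lengths[ch] < 2L * edgeMargin + L) next
            s0 <- sample.int(lengths[ch] - 2L * edgeMargin - L, 1) +
                edgeMargin
            near <- planted$chrom == ch &
                abs(planted$start0 - s0) < minSeparation
            if (any(near)) next
            chroms[[ch]][(s0 + 1L):(s0 + L)] <- motif
            planted <- rbind(planted,
                             data.frame(chrom = ch, start0 = s0, len = L))
            placed <- placed + 1L
        }
    }

    genome <- Biostrings::DNAStringSet(vapply(chroms, paste0, character(1),
                                              collapse = ""))
    names(genome) <- names(lengths)

    ## scrub accidental motif occurrences (either strand), keeping planted
    for (item in embed) {
        enz <- item$enzyme
        L <- nchar(enz@recognition)
        for (iter in 1:25) {
            found <- findCutSites(genome, enz)
            fs <- data.frame(chrom = as.character(GenomicRanges::seqnames(found)),
                             cut0 = cutPos0(found))
            ## map each found cut back to candidate motif starts and mark
            ## those overlapping a planted motif of any enzyme
            keepPlanted <- rep(FALSE, nrow(fs))
            for (k in seq_len(nrow(fs)))
                keepPlanted[k] <- any(planted$chrom == fs$chrom[k] &
                    fs$cut0[k] > planted$start0 &
                    fs$cut0[k] < planted$start0 + planted$len)
            stray <- fs[!keepPlanted, , drop = FALSE]
            if (!nrow(stray)) break
            seqs <- strsplit(as.character(genome), "")
            for (k in seq_len(nrow(stray))) {
                ## mutate one base near the stray cut, away from planted spans
                p0 <- stray$cut0[k]
                cand <- (p0 - L):(p0 + L)
                cand <- cand[cand >= 1 & cand <= lengths[stray$chrom[k]] - 1]
                inPlanted <- vapply(cand, function(x)
                    any(planted$chrom == stray$chrom[k] &
                        x >= planted$start0 &
                        x < planted$start0 + planted$len), logical(1))
                cand <- cand[!inPlanted]
                if (!length(cand)) next
                x <- cand[ceiling(length(cand) / 2)]
                cur <- seqs[[stray$chrom[k]]][x + 1L]
                seqs[[stray$chrom[k]]][x + 1L] <-
                    sample(setdiff(c("A", "C", "G", "T"), cur), 1)
            }
            genome <- Biostrings::DNAStringSet(
                vapply(seqs, paste0, character(1), collapse = ""))
            names(genome) <- names(lengths)
        }
    }

    sites <- NULL
    for (item in embed) {
        s <- findCutSites(genome, item$enzyme)
        sites <- if (is.null(sites)) s else c(sites, s)
    }
    if (is.null(sites))
        sites <- GenomicRanges::GRanges(seqinfo = .genomeSeqinfo(genome))
    list(genome = genome, sites = BiocGenerics::sort(sites))
}

#' Draw per-site cutting efficiencies around a nominal value
#'
#' Real digests cut different recognition sites with different efficiencies;
#' this models that site-to-site variability as logit-normal scatter around
#' the nominal efficiency. On the logit scale the spread is constant, so
#' the absolute spread shrinks near 0 and 1 -- the regime where the
#' read/efficiency correlation degrades because counting noise overtakes
#' true between-site variation.
#'
#' @param fBar nominal cutting efficiency.
#' @param nSites number of sites.
#' @param tau SD of the logit-scale scatter (default 0.3).
#' @param seed RNG seed.
#' @return numeric vector of per-site efficiencies in (0, 1).
#' @export
spreadEfficiencies <- function(fBar, nSites, tau = 0.3, seed = 1L) {
    set.seed(seed)
    stopifnot(fBar > 0, fBar < 1)
    stats::plogis(stats::qlogis(fBar) + stats::rnorm(nSites, 0, tau))
}

#' Simulate a paired-end gDNA fragment library around cut sites
#'
#' Emits, for each cut site, a locally uniform coverage patch of molecules
#' whose span can interact with the counting vicinity; molecules covering
#' the cut are cleaved with probability \code{fCut}, producing two fragments
#' whose ends abut the cut within a 1 bp sequencer jitter, otherwise they
#' remain as spanning fragments. A genome-wide uniform sonication background
#' is added, from which the background efficiency \code{f_bg} can be
#' estimated. Local uniformity of coverage around the cut preserves the
#' fragment-end geometry that the background-window estimator subtracts.
#'
#' @param genome \code{DNAStringSet}.
#' @param sites cut-site \code{GRanges}.
#' @param fCut per-site cutting efficiency in \[0, 1\] (scalar recycled).
#' @param coverage expected number of molecules covering each cut site
#'   (default 300, a deep gDNA library for a small genome).
#' @param fragMean,fragSd fragment length distribution, normal(400, 80)
#'   truncated to \[100, 700\] bp (sonication-sized fragments).
#' @param sonicationRate background fragments per bp of genome (default
#'   0.05).
#' @param seed RNG seed.
#' @return list with \code{fragments} (\code{GRanges}) and \code{truth}
#'   (planted parameters).
#' @export
simulateGdna <- function(genome, sites, fCut, coverage = 300,
                         fragMean = 400, fragSd = 80,
                         sonicationRate = 0.05, seed = 1L) {
    set.seed(seed)
    stopifnot(all(fCut >= 0 & fCut <= 1))
    fCut <- rep_len(fCut, length(sites))
    lens <- genomeLengths(genome)
    minLen <- 100L
    maxLen <- 700L
    w <- if (length(sites) && !is.null(sites$vicinity))
        max(sites$vicinity) else 3L

    rlen <- function(n) {
        L <- as.integer(round(stats::rnorm(n, fragMean, fragSd)))
        pmin(pmax(L, minLen), maxLen)
    }

    out <- vector("list", 2L * length(sites) + 1L)
    ## the sonication background already provides fragMean * sonicationRate
    ## molecules of coverage everywhere, including across the cut sites; the
    ## site patches top the local coverage up to the requested depth so the
    ## site neighbourhood sees exactly one uniformly sheared library
    patchCov <- max(coverage - fragMean * sonicationRate, 0)
    if (length(sites)) {
        chr <- as.character(GenomicRanges::seqnames(sites))
        c0 <- cutPos0(sites)
        for (i in seq_along(sites)) {
            lo <- c0[i] - maxLen - 10L
            hi <- c0[i] + w + 2L
            span <- hi - lo + 1L
            n <- stats::rpois(1, patchCov * span / fragMean)
            if (n == 0L) next
            s0 <- lo + sample.int(span, n, replace = TRUE) - 1L
            L <- rlen(n)
            e0 <- s0 + L
            covering <- s0 <= c0[i] - 1L & e0 >= c0[i] + 1L
            cut <- covering & stats::runif(n) < fCut[i]
            j <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
            bp <- pmin(pmax(c0[i] + j, s0 + 1L), e0 - 1L)
            ks <- c(s0[!cut], s0[cut], bp[cut])
            ke <- c(e0[!cut], bp[cut], e0[cut])
            out[[i]] <- data.frame(chrom = chr[i], s0 = ks, e0 = ke)
        }
    }
    totalLen <- sum(as.numeric(lens))
    nb <- stats::rpois(1, sonicationRate * totalLen)
    if (nb > 0L) {
        ch <- sample(names(lens), nb, replace = TRUE, prob = lens)
        L <- rlen(nb)
        s0 <- as.integer(floor(stats::runif(nb, 0, lens[ch] - L)))
        e0 <- s0 + L
        ## background molecules spanning a cut are cleaved like any other
        if (length(sites)) {
            chrS <- as.character(GenomicRanges::seqnames(sites))
            c0 <- cutPos0(sites)
            for (i in seq_along(sites)) {
                covering <- which(ch == chrS[i] & s0 <= c0[i] - 1L &
                                      e0 >= c0[i] + 1L)
                if (!length(covering)) next
                cut <- covering[stats::runif(length(covering)) < fCut[i]]
                if (!length(cut)) next
                j <- sample(c(-1L, 0L, 1L), length(cut), replace = TRUE)
                bp <- pmin(pmax(c0[i] + j, s0[cut] + 1L), e0[cut] - 1L)
                out[[length(sites) + 1L + i]] <-
                    data.frame(chrom = chrS[i], s0 = bp, e0 = e0[cut])
                e0[cut] <- bp
            }
        }
        out[[length(sites) + 1L]] <- data.frame(chrom = ch, s0 = s0,
                                                e0 = e0)
    }
    df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(df))
        df <- data.frame(chrom = character(), s0 = integer(), e0 = integer())
    ## clip to chromosome bounds, drop degenerate slivers
    df$s0 <- pmax(df$s0, 0L)
    df$e0 <- pmin(df$e0, lens[df$chrom])
    df <- df[df$e0 - df$s0 >= 20L, , drop = FALSE]
    frags <- GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$s0 + 1L, end = df$e0),
        seqinfo = .genomeSeqinfo(genome))
    list(fragments = frags,
         truth = list(fCut = fCut, coverage = coverage,
                      sonicationRate = sonicationRate, seed = seed))
}

.telomereSeqs <- function(n, readLength) {
    one <- function() {
        parts <- character()
        left <- readLength
        while (left > 11L) {
            a <- sample(0:3, 1)
            b <- sample(1:10, 1)
            if (a + 1L + b > left - 2L) next
            parts <- c(parts, paste0(strrep("C", a), "A", strrep("C", b)))
            left <- left - (a + 1L + b)
        }
        ## final unit sized to fit exactly: C^a A C^b with a+1+b == left
        b <- min(10L, left - 1L)
        a <- left - 1L - b
        parts <- c(parts, paste0(strrep("C", a), "A", strrep("C", b)))
        paste0(parts, collapse = "")
    }
    vapply(seq_len(n), function(i) one(), character(1))
}

#' Simulate a DSB-labeled read set
#'
#' Emits proximal-barcode-style reads whose 5' ends sit at break positions:
#' spike-in reads at each enzyme cut site with expected count
#' \code{alpha * fCut * p} facing the cut from both sides, two-ended studied
#' breaks with reads on both strands, one-ended breaks with single-strand
#' polarity, uniform background reads, and optionally telomere-motif reads
#' whose sequences match the CAC-repeat rule.
#'
#' @param genome \code{DNAStringSet}.
#' @param sites cut-site \code{GRanges} (spike-ins).
#' @param fCut per-site cutting efficiency (scalar recycled).
#' @param landscape a [BreakLandscape-class]; \code{NULL} for spike-ins only.
#' @param alpha labeled reads per DSB (the planted proportionality
#'   coefficient).
#' @param p proportion of digested cells.
#' @param readLength read length in bp (default 50).
#' @param seed RNG seed.
#' @param withSequences attach genomic sequences to all reads (telomere
#'   reads always carry their synthetic sequence).
#' @return list with \code{reads} (stranded \code{GRanges}, metadata column
#'   \code{seq}) and \code{truth} (planted alpha, per-site expectations and
#'   the planted studied break frequency per cell).
#' @export
simulateDsbReads <- function(genome, sites, fCut, landscape = NULL,
                             alpha = 500, p = 1, readLength = 50L,
                             seed = 1L, withSequences = FALSE) {
    set.seed(seed)
    stopifnot(alpha > 0, p > 0, p <= 1)
    if (is.null(landscape)) landscape <- breakLandscape()
    validObject(landscape)
    fCut <- rep_len(fCut, length(sites))
    lens <- genomeLengths(genome)

    rows <- list()
    emit <- function(chrom, p5, strand) {
        ## p5 = 0-based coordinate of the read 5' base; strand may be a
        ## scalar or a per-read vector
        strand <- rep_len(strand, length(p5))
        s0 <- ifelse(strand == "+", p5, p5 - readLength + 1L)
        data.frame(chrom = rep_len(chrom, length(p5)), s0 = s0,
                   strand = strand)
    }

    ## spike-in reads: both strands face the cut
    if (length(sites)) {
        chr <- as.character(GenomicRanges::seqnames(sites))
        c0 <- cutPos0(sites)
        nspike <- stats::rpois(length(sites), alpha * fCut * p)
        for (i in seq_along(sites)) {
            n <- nspike[i]
            if (n == 0L) next
            nw <- stats::rbinom(1, n, 0.5)
            jit <- function(k) sample(c(-1L, 0L, 1L), k, replace = TRUE)
            rows[[length(rows) + 1L]] <-
                rbind(emit(chr[i], c0[i] + jit(nw), "+"),
                      emit(chr[i], c0[i] - 1L + jit(n - nw), "-"))
        }
    }

    twoE <- landscape@twoEnded
    for (k in seq_len(nrow(twoE))) {
        n <- stats::rpois(1, alpha * twoE$freq[k])
        if (n == 0L) next
        nw <- stats::rbinom(1, n, 0.5)
        jw <- sample(-2:2, nw, replace = TRUE)
        jc <- sample(-2:2, n - nw, replace = TRUE)
        rows[[length(rows) + 1L]] <-
            rbind(emit(twoE$chrom[k], twoE$pos[k] + jw, "+"),
                  emit(twoE$chrom[k], twoE$pos[k] - 1L + jc, "-"))
    }

    oneE <- landscape@oneEnded
    for (k in seq_len(nrow(oneE))) {
        n <- stats::rpois(1, alpha * oneE$freq[k])
        if (n == 0L) next
        j <- sample(-2:2, n, replace = TRUE)
        p5 <- if (oneE$polarity[k] == "+") oneE$pos[k] + j
              else oneE$pos[k] - 1L + j
        rows[[length(rows) + 1L]] <- emit(oneE$chrom[k], p5,
                                          oneE$polarity[k])
    }

    totalLen <- sum(as.numeric(lens))
    nbg <- stats::rpois(1, alpha * landscape@uniformBackground * totalLen)
    if (nbg > 0L) {
        ch <- sample(names(lens), nbg, replace = TRUE, prob = lens)
        pos <- as.integer(floor(stats::runif(nbg, readLength,
                                             lens[ch] - readLength)))
        rows[[length(rows) + 1L]] <-
            emit(ch, pos, sample(c("+", "-"), nbg, replace = TRUE))
    }

    df <- do.call(rbind, rows)
    if (is.null(df))
        df <- data.frame(chrom = character(), s0 = integer(),
                         strand = character())
    df$s0 <- pmax(df$s0, 0L)
    df$e0 <- pmin(df$s0 + readLength, lens[df$chrom])
    df$seq <- NA_character_

    ## telomere-motif reads at chromosome ends
    tf <- landscape@telomereReadFraction
    if (tf > 0) {
        ntel <- round(tf / (1 - tf) * nrow(df))
        if (ntel > 0) {
            ch <- sample(names(lens), ntel, replace = TRUE)
            atStart <- stats::runif(ntel) < 0.5
            s0 <- ifelse(atStart,
                         sample.int(150L, ntel, replace = TRUE) - 1L,
                         lens[ch] - readLength -
                             sample.int(150L, ntel, replace = TRUE))
            seqs <- .telomereSeqs(ntel, readLength)
            flip <- stats::runif(ntel) < 0.5
            seqs[flip] <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAStringSet(seqs[flip])))
            tel <- data.frame(chrom = ch, s0 = pmax(s0, 0L),
                              strand = sample(c("+", "-"), ntel,
                                              replace = TRUE))
            tel$e0 <- pmin(tel$s0 + readLength, lens[tel$chrom])
            tel$seq <- seqs
            df <- rbind(df, tel)
        }
    }

    reads <- GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$s0 + 1L, end = df$e0),
        strand = df$strand,
        seqinfo = .genomeSeqinfo(genome))
    mcols(reads)$seq <- df$seq
    if (withSequences && length(reads)) {
        need <- is.na(mcols(reads)$seq)
        if (any(need))
            mcols(reads)$seq[need] <- as.character(
                Biostrings::getSeq(genome, reads[need]))
    }

    bPlanted <- sum(twoE$freq) + sum(oneE$freq) +
        landscape@uniformBackground * totalLen
    list(reads = reads,
         truth = list(alpha = alpha, fCut = fCut, p = p,
                      bStudiedPlanted = bPlanted,
                      expectedSpikeReads = alpha * sum(fCut) * p,
                      seed = seed))
}

#' Simulate a UMI-tagged read table
#'
#' Each true break event emits one unique (position, UMI) record plus PCR
#' duplicates; exact-match deduplication therefore recovers the break count
#' up to UMI collisions.
#'
#' @param sites cut-site \code{GRanges} (break positions).
#' @param dsbsPerCellPerSite per-cell break frequency per site (scalar
#'   recycled).
#' @param nCells number of cells in the sample.
#' @param umiLength UMI length in nt (>= 4; default 8).
#' @param duplicationRate expected PCR duplicates per unique record
#'   (Poisson; default 0.3).
#' @param positionJitter breaks land within +/- this many bp of the site.
#' @param barcode sample barcode attached to every record.
#' @param seed RNG seed.
#' @return list with \code{umis} (data.frame chrom, pos, umi, barcode;
#'   \code{pos} 0-based) and \code{truth} (expected and realized break
#'   counts).
#' @export
simulateUmiReads <- function(sites, dsbsPerCellPerSite, nCells,
                             umiLength = 8L, duplicationRate = 0.3,
                             positionJitter = 20L, barcode = "CATCACGC",
                             seed = 1L) {
    set.seed(seed)
    if (umiLength < 4L) stop("umiLength must be >= 4")
    dsbs <- rep_len(dsbsPerCellPerSite, length(sites))
    chr <- as.character(GenomicRanges::seqnames(sites))
    c0 <- cutPos0(sites)
    nb <- stats::rpois(length(sites), dsbs * nCells)
    total <- sum(nb)
    if (total == 0L) {
        umis <- data.frame(chrom = character(), pos = integer(),
                           umi = character(), barcode = character())
    } else {
        chrom <- rep(chr, nb)
        pos <- rep(c0, nb) +
            sample(seq(-positionJitter, positionJitter), total,
                   replace = TRUE)
        umi <- vapply(seq_len(total), function(i)
            paste0(sample(c("A", "C", "G", "T"), umiLength,
                          replace = TRUE), collapse = ""), character(1))
        copies <- 1L + stats::rpois(total, duplicationRate)
        idx <- rep(seq_len(total), copies)
        umis <- data.frame(chrom = chrom[idx], pos = pos[idx],
                           umi = umi[idx], barcode = barcode,
                           stringsAsFactors = FALSE)
        umis <- umis[sample.int(nrow(umis)), , drop = FALSE]
        rownames(umis) <- NULL
    }
    list(umis = umis,
         truth = list(breaksExpected = sum(dsbs) * nCells,
                      breaksActual = total, seed = seed))
}
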