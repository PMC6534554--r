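Package: DSBquant
Title: Absolute Quantification of DNA Double-Strand Breaks from Spike-In
    Sequencing Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements spike-in based absolute quantification of DNA
    double-strand breaks (DSBs) from break-labeling sequencing data.
    Restriction-enzyme cutting efficiencies are estimated from paired-end
    genomic DNA fragments (or qPCR threshold cycles), converted into
    spike-in break frequencies, and used to calibrate labeled read counts
    into DSBs per cell. Includes in-silico digestion, telomere/rDNA read
    filtering, sliding-window break-density tracks with replication
    background removal, strand-asymmetry detection of one-ended
    (replication-associated) DSBs, hypergeometric fragile-region and
    permutation-based annotation enrichment tests, UMI-based break
    counting for cross-method comparison, and a synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    Rsamtools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, Coverage, DNADamage, Normalization, Software
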