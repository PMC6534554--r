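---
title: "Absolute DSB quantification with enzyme spike-ins"
author: "DSBquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute DSB quantification with enzyme spike-ins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DSBquant)
library(GenomicRanges)
```

## The quantification problem

Break-labeling sequencing assays (BLESS, i-BLESS, END-seq, Break-Seq and
relatives) capture DNA double-strand break (DSB) ends and sequence reads
whose 5' termini sit directly at break positions. Raw read counts, however,
only describe the *distribution* of breaks: the number of reads per locus
depends on labeling efficiency, library yield and sequencing depth, so two
samples cannot be compared on an absolute scale, and a uniform genome-wide
induction of breaks is invisible after the usual normalization to total read
count.

The spike-in strategy implemented here solves this by digesting the sample
(in vitro, or in vivo via an expressed endonuclease) with a restriction
enzyme before labeling. The enzyme creates breaks at known recognition
sites at a measurable per-molecule frequency, which turns read counts into
an absolute scale:

* cutting efficiency $f_{cut}$ — the fraction of molecules cleaved at the
  recognition sites, measured from paired-end genomic DNA (gDNA)
  sequencing or qPCR;
* spike-in breaks per cell $B_{cut} = f_{cut} \, N_{sites} \, p$, where
  $p$ is the proportion of digested cells;
* reads per break $\alpha = R_{cut} / B_{cut}$, with $R_{cut}$ the labeled
  reads at the cutting sites;
* studied breaks per cell $B_{studied} = R_{studied} / \alpha$, with
  $R_{studied}$ the labeled reads left after removing cut-site, telomeric
  and rDNA/masked reads.

Because $\alpha$ cancels sequencing depth, $B_{studied}$ is — in
expectation — invariant to subsampling the labeled library, which is the
decisive advantage over counting unique molecular identifiers (UMIs),
whose totals scale directly with depth.

## Estimating cutting efficiency from gDNA fragments

A paired-end gDNA fragment is classified at a cut site with vicinity
half-width $w$ (default 3 bp — a few-nucleotide window around the
canonical scission, configurable because the effective width is
empirically determined per enzyme and dataset):

* **cut** if either fragment end falls inside $[c - w,\, c + w]$ around
  the cut coordinate $c$ (a cleaved molecule leaves a terminus at the
  cut);
* **uncut** if the fragment spans the whole vicinity with both ends
  outside;
* ignored otherwise.

Each cleaved molecule yields two observable fragments while an intact one
yields a single spanning fragment, hence the molecule-fraction estimator

$$f_{cut} = \frac{N_{cut}}{N_{cut} + 2\,N_{uncut}} - f_{bg},$$

pooled over sites (for multi-site enzymes) after dropping sites with at
most `minReads` (default 100) classified fragments or non-positive
background-subtracted efficiency. The background term $f_{bg}$ is the same
ratio evaluated at pseudo-sites placed in 1500 random windows (the
conventional 1000–2000 range) away from any real site: random shear ends
land inside a vicinity by chance at a rate of roughly
$(4w + 2)/\bar{L}$ per covering molecule, and $f_{bg}$ measures exactly
that contamination.

Uncertainty is decomposed as
$\sigma_{total} = \sqrt{\sigma_{bg}^2 + \sigma_{Poisson}^2}$: a Poisson
counting term obtained by perturbing $N_{cut}$ and $N_{uncut}$ by one
standard deviation in opposite directions, and the standard deviation of
the per-window background values. The latter is intentionally a
*per-window spread*, not a standard error of the mean — the resulting
interval is conservative, which matches how the per-site spread of
single-site quantifications is reported as a conservative SD of
$B_{studied}$.

Two numerical notes:

* The estimator has a small negative bias (order 1–5% relative) under a
  realistic generative model: a molecule cleaved within ~20 bp of one of
  its shear ends produces a fragment too short to map, so a fraction of
  cut molecules contribute one fragment instead of two, and the constant
  $f_{bg}$ subtraction over-corrects slightly at high $f_{cut}$ because
  cleavage removes some of the chance shear ends the background window
  model assumes. Both effects stay well inside $3\sigma_{total}$ at all
  tested efficiencies.
* `poissonSD` requires $N_{cut}, N_{uncut} \ge 1$; the approximation is
  undefined below that and the function errors rather than extrapolating.

With qPCR instead of gDNA, $f_{cut} = 1 - 2^{-\Delta C_T}$ with
$\Delta C_T = C_T(\text{digested}) - C_T(\text{undigested})$, averaged
over dilutions; an optional per-dilution calibration offset supports
empirical correction of $\Delta C_T$. Negative $\Delta C_T$ is clamped to
zero with a warning.

## The optimal cutting-efficiency range

Quantification assumes labeled reads are proportional to break frequency.
`linearityCheck` tests this on the spike-ins themselves: Pearson
correlation between per-site labeled reads and per-site efficiencies, with
$r \le 0.5$ flagged as weak. Site-to-site efficiency variation is the
signal behind this correlation; it collapses near $f_{cut} \to 0$ (few cut
fragments, estimates dominated by counting noise) and near
$f_{cut} \to 1$ (few uncut fragments, and true between-site spread
compressed against the upper bound). The package's validation reproduces
this as a property: at a realistic gDNA depth (300 molecules per site) and
labeled-library yield ($\alpha = 500$ reads per break), median $r$ across
seeds exceeds 0.5 for nominal efficiencies of 12–62%, collapses toward
zero at 95%, and becomes weak and unstable at 2% (median around 0.3–0.4,
with individual seed sets straddling the 0.5 mark).

## Filtering studied reads

`filterStudiedReads` removes, in priority order (each read once):
reads assigned to cut-site vicinities; telomeric reads, defined as reads
whose full sequence (or its reverse complement — the AC-rich strand) is a
chain of `C{0,3}AC{1,10}` repeat units; and reads overlapping rDNA or
custom mask intervals. The audit table always satisfies input = output +
removed.

## Tracks, replication background, and sample comparison

`windowDensity` converts filtered read 5' ends into DSBs per cell (or per
million cells) in sliding windows (500 bp window, 50 bp step by default).
For replication-associated signal, the genome-wide modal density is taken
as non-replicative background: the histogram mode (Freedman–Diaconis bin
width, floored at the discrete value lattice that counts-over-alpha values
live on; ties resolved to the lowest bin; the mode reported as the median
of values in the modal bin) is subtracted and negatives are clamped to
zero.

`compareSamplesPoisson` compares two samples after normalizing the treated
counts by the ratio of the spike-in coefficients: a window is enriched
when the normalized treated count exceeds the control count by more than 5
Poisson standard deviations (a deliberately conservative rule), with a
one-sided hypergeometric p-value (Bonferroni-corrected) reported
alongside. The hypergeometric term sees only *relative* redistribution of
reads — a uniform global induction is detectable only through the
spike-in-normalized 5-SD rule, which is the point of the method.

## One-ended DSBs from strand asymmetry

A two-ended break exposes both a Watson-facing and a Crick-facing end and
labels both strands around its position; a broken replication fork has a
single double-strand end and labels one strand only. `oneEndedTest` tiles
the genome with non-overlapping 500 nt windows (non-overlapping so the
Bonferroni correction over windows × two one-sided tests is valid),
computes for each window the hypergeometric tail probability of its Watson
(and, separately, Crick) count when drawing $W + C$ reads from the
genome-wide strand totals (the urn), and calls a window one-ended when the
corrected p-value is below $10^{-10}$. The threshold is applied after
correction; a flag restores the pre-correction convention. Adjacent
significant windows of the same polarity are merged — one broken fork can
straddle a window boundary — and the one-ended break frequency is
$\sum |W - C| / \alpha$, optionally restricted to an annotation such as
±10 kb around replication origins.

## Fragile regions and annotation enrichment

`fragileRegions` applies the same hypergeometric machinery
treatment-vs-control over mappable windows with Benjamini–Hochberg
correction (significance at q < 0.05, the corrected version of the global
P < 0.05 convention). `annotationEnrichment` scores an annotation by the
ratio of mappable-nucleotide fractions (regions ∩ annotation over regions,
divided by annotation over genome) and builds the null by re-placing the
regions uniformly — length-preserving — within mappable space; with 1000
permutations the empirical p-value is bounded below by 1/1001. When no
mappability track is supplied, the whole genome is treated as mappable.

## UMI-based counting (BLISS-style)

For cross-method comparison, `dedupUmis` collapses records by exact match
on (chromosome, position, UMI) — no edit-distance clustering — after
barcode filtering; `countUmisNearSites` counts unique UMIs within ±100 bp
of sites, merging sites closer than 200 bp so nothing is double-counted
and excluding chrY (absent in female-derived cell lines); and
`blissDsbsPerCell` divides by cell count with a Poisson-spread SD. The
depth-invariance property test thins the raw UMI table to 10% and observes
the UMI total collapse by roughly the thinning factor while the paired
spike-in estimate moves by well under 5% — the instability that motivates
spike-in calibration.

## What the simulator emulates

`simulateGenome` plants exact motif occurrences in random sequence (38%
GC, yeast-like) and scrubs chance occurrences, so in-silico digestion
recovers the planted truth. `simulateGdna` models one uniformly sheared
library: fragment lengths normal(400, 80) truncated to 100–700 bp
(sonication-sized; the truncation bounds are the plausible mapping range),
a genome-wide background at 0.05 fragments/bp, and site-local coverage
topped up to the requested depth (default 300 molecules per site, a deep
library for a small genome) by patches of molecules whose span can
interact with the counting vicinity. Patches are locally uniform, and
background molecules crossing a cut are cleaved like any other, so the
fragment-end geometry around sites matches what the background-window
estimator subtracts; this reproduces full-genome simulation statistics at
a small fraction of the cost. Cleaved ends abut the cut within a 1 bp
sequencer jitter. `simulateDsbReads` emits Poisson read counts per source
(spike-ins facing the cut from both strands, two-ended breaks on both
strands, one-ended breaks on a single strand, uniform background,
telomere-motif reads built as exact CAC-repeat chains), with per-site
efficiencies optionally scattered logit-normally (`spreadEfficiencies`,
τ = 0.3) around the nominal value. `simulateUmiReads` emits one unique
(position, UMI) per break plus Poisson PCR duplicates (default rate 0.3
duplicates per molecule).

Deliberately not modeled: sequencing errors, mappability structure, GC
bias, resection gradients around one-ended breaks (signal can spread
kilobases from in vivo cut sites; only the configurable vicinity width
acknowledges this), and enzyme star activity or methylation sensitivity.
Passing recovery tests on these simulations therefore demonstrates the
estimators' correctness under the stated generative model, not robustness
to alignment artifacts in real libraries.

Determinism: every generator takes a seed and sets the RNG once at entry;
emission order is fixed by construction, so equal seeds give byte-identical
outputs.

## Validation problem sizes

The standard validation conditions, chosen to finish in minutes on one
core while leaving comfortable statistical margins: a 1 Mb genome with 20
spike-in sites; recovery grids at planted $f_{cut} \in \{0.12, 0.30,
0.62\}$ and $B_{studied} \in \{1, 10, 150\}$ DSBs/cell with 10⁴ molecules
per site of gDNA coverage and a deep labeled library ($\alpha = 2000$) so
that read noise does not mask estimator bias; linearity runs at the
realistic depth above; one-ended recovery on 2 Mb with 100 origins at 0.5
one-ended DSBs each. Cross-checks use independent oracles: longhand
hypergeometric enumeration, a step-up BH implementation, dense
deterministic background windowing, and closed-form hand evaluations.

## Known limitations

* The efficiency estimator's small negative bias (size selection and the
  constant-background approximation, above) is inherited by $B_{studied}$;
  it is bounded by the reported $\sigma_{total}$ and by the ±15% recovery
  envelope in the validation suite.
* $\alpha$ is a single genome-wide constant; locus-specific labeling
  differences are averaged over.
* The per-site SD of $B_{studied}$ requires at least two usable sites;
  single-site designs fall back to propagating the efficiency SD through
  the quotient rule.
* The one-ended urn is the genome-wide strand composition; local
  composition shifts (e.g. rDNA) should be masked before testing.
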