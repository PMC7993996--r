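---
title: "Methods: replication-program analysis with repliseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replication-program analysis with repliseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliseg)
```

# The measurement and the model

Strand-oriented Okazaki-fragment sequencing (OK-seq) counts, per
fixed-width genomic bin, the fragments mapping to the reverse (`R`) and
forward (`F`) strand. Because Okazaki fragments are synthesised on the
lagging strand, the replication fork directionality

$$\mathrm{RFD} = \frac{R - F}{R + F} \in [-1, 1]$$

measures the population-averaged direction of fork movement at each
locus: +1 when every cell replicates the locus with a rightward-moving
fork, -1 leftward, 0 when directions balance. In mammalian genomes the
profile is piecewise-quasi-linear. Upward shifts extending over tens of
kilobases are zones where replication preferentially initiates
(ascending segments, ASs); downward shifts are predominant termination
zones (DSs); long plateaus at |RFD| > 0.8 are unidirectionally
replicating regions (URRs, passively replicated by forks from one
side); long plateaus at |RFD| near 0 are null-RFD regions (NRRs),
consistent with spatially random initiation and termination.

Replicates are pooled by summing counts before the ratio is taken, so
the pooled RFD is the coverage-weighted mean of replicate RFDs. The
replicate quality control recomputes RFD in 50-kb windows from summed
counts and reports the Pearson correlation over windows with more than
100 mapped reads in both replicates; deeply sequenced biological
replicates reach r above 0.95, which the OK-seq simulation in this
package reproduces.

# Segment detection

## Convexity

ASs and DSs are delineated from the *convexity* of the profile: the
convolution of the RFD track with the second derivative of a Gaussian
of standard deviation $\sigma$ = 32 kb (kernel truncated at $\pm 4
\sigma$, discretely mean-centred so constant profiles map to exactly
zero). For an ascending shift the convexity forms a positive extremum
upstream of the shift midpoint and a negative extremum downstream; a
descending shift does the opposite. The bin width must be at most
$\sigma/8$ (1 kb against the 32-kb default) so the kernel is well
sampled.

The amplitude threshold separating genuine shift extrema from noise is
`2 * 1.4826 * MAD` of the genome-wide convexity track by default: a
scale-free, robust criterion that adapts to sequencing depth. It is
exposed as `amp_threshold` for users who want to reproduce a specific
conservative setting.

## Pairing rule

Each *immediately adjacent* (positive, negative) super-threshold
extremum pair bounds one AS and each (negative, positive) pair one DS;
extrema below the threshold are ignored, and same-sign neighbours bound
nothing. We deliberately do not merge same-sign runs onto their largest
member: a sharp termination transition sitting upstream of an
initiation zone can carry a larger positive extremum than the zone's
own, and merging would then drag the AS border ~100 kb upstream of the
initiation zone. With adjacent-opposite-sign pairing, every planted
initiation zone in the synthetic validation is recovered with its
midpoint within one bin of the ideal position, and the rule is
symmetric, so negating the profile exactly swaps the AS and DS lists.

## RFD shift and filters

Segments are annotated with the RFD shift
$\Delta\mathrm{RFD} = \mathrm{RFD}(pos_{3'}) - \mathrm{RFD}(pos_{5'})$,
a direct measure of initiation efficiency (an isolated zone that fires
in every cell shifts RFD from -1 to +1, $\Delta$RFD = 2). Border RFD is
estimated as the mean over one $\sigma$ immediately outside the border
rather than a single bin, because single-bin RFD at depth ~100
fragments has a standard error near 0.1. Downstream analyses keep
segments strictly longer than 20 kb with $\Delta$RFD strictly above
0.5; both inequalities are strict so boundary values are excluded
reproducibly.

## Constant-RFD regions and timing domains

URRs are maximal runs of bins with |RFD| > 0.8 spanning at least
300 kb; NRRs |RFD| < 0.15 over at least 500 kb. Missing bins break
runs; no smoothing is applied, so these calls are intended for deeply
sequenced, pooled profiles (at 100 fragments per bin the per-bin noise
fragments the runs, which is visible in the synthetic experiments and
is a property of the thresholds, not a defect of the caller).

Replication timing uses pre-computed log2(Early/Late) tracks at 10-kb
bins, smoothed by a centred 100-kb moving mean. Because 100 kb spans an
even number of 10-kb bins the window is tied to the lower side (bins
$i-5 \dots i+4$); the choice is arbitrary but fixed and documented.
Early timing domains are maximal runs with smoothed value strictly
above 1.6, late domains strictly below -2.0. Run calling reports every
maximal run; an optional `merge_gap` closes small gaps for users who
prefer fewer, larger domains (off by default, since the plain
procedure is the reproducible baseline).

# ChIP quantification and transcription

Replicate counts are summed per bin, scaled by the genome-wide mean
over complete bins (the trailing partial bin of each chromosome is kept
but excluded from means), and divided by the identically scaled input.
Bins with zero input reads are removed from *all* samples of a run
through a shared mask so bin sets stay comparable across factors.
Zero-count bins elsewhere are real observations and enter the
normalisation mean. Note that a ratio of two Poisson-noisy tracks
carries a Jensen bias of roughly 1/depth above 1 even without
structure; aggregate analyses divide *after* averaging precisely to
avoid compounding this per-bin bias (`border_profile` and
`gene_metaprofile` report mean(sample)/mean(input) per offset, with the
mean-of-ratios variant available for comparison).

TPM is computed as $10^6 (n_j/l_j) / \sum_i (n_i/l_i)$ from read counts
and exonic lengths in kb. Activity classes split at 3, 10 and 40 TPM
with half-open, lower-inclusive intervals (a gene at exactly 3 TPM is
`low`): the boundaries themselves are conventions and one consistent
rule is applied everywhere. When replicate RNA-seq samples are
available, per-replicate TPMs are averaged rather than pooled, keeping
each library's length normalisation intact.

For distribution analyses, 10-kb windows are categorised as intergenic
(every gene more than 5 kb away), silent or expressed gene body (fully
inside a gene with TPM < 3 or > 3, more than 3 kb from both gene ends),
or excluded; the margins drop TSS- and TTS-proximal signal by
construction. AS classification extends each segment by 20 kb: no
overlapping gene makes it non-genic; expressed genes (TPM > 3) whose
body lies within 20 kb of both borders make it type 1, of exactly one
border type 2 (mirrored so the expressed border is on the right), and
genic segments qualifying at neither border are kept as an explicit
fourth class rather than silently dropped, so class counts always sum
to the total.

# Aggregates, histograms and tests

Locus-aligned profiles (AS borders from 50 kb outside to 10 kb inside;
TSS/TTS metagenes for genes longer than 30 kb with no neighbour within
15 kb, oriented by strand) report the across-locus mean with a
$\pm 2 \times$ SEM band. The timing-decile histograms place 10-kb
windows into deciles of the genome-wide smoothed timing distribution
and, per decile, estimate the probability distribution of ChIP relative
frequency over 50 equal bins on [0, P99.5] plus an overflow bin (the
fixed axis rule makes panels comparable); columns are normalised to
sum to 1, and windows must lie fully inside any region-type
restriction, so windows straddling segment edges are excluded.

Distribution comparisons use the two-sample Kolmogorov-Smirnov
statistic $D$ with the sample-size correction
$Z = D\sqrt{nm/(n+m)}$, evaluated exactly at both one-sided limits of
the pooled points; one-sided Welch t-tests (Satterthwaite degrees of
freedom; two zero-variance groups with equal means return p = 0.5 by
convention); and one-way ANOVA with Tukey HSD at 95% family-wise
confidence.

# The shuffling null

Interval sets (e.g. candidate regulatory elements) are compared to
chance by re-placing every interval uniformly at random within its own
chromosome, preserving counts and lengths exactly and rejecting
placements that touch assembly gaps (runs of more than 20 Ns from
`n_gap_mask`), with a retry cap of 1e4 per interval. Placed intervals
may overlap one another by default (the minimal-assumption null); a
stricter non-overlapping null is available. Aggregate RFD profiles
around interval centres report a 95% envelope; the band is the standard
error form $1.96\,\mathrm{sd}/\sqrt{n}$ by default, with the plain
$1.96\,\mathrm{sd}$ population band behind `band = "sd"` since either
reading of a "mean and standard deviation" envelope is defensible.

# The synthetic genome

`build_genome()` plants a replication architecture with known truth so
each stage can be scored. Per chromosome (default: one 50-Mb chromosome
at 1-kb bins):

- 30 initiation zones of 30-60 kb with efficiencies spread evenly over
  [0.3, 1], placed at least 450 kb apart; configured fractions are
  flanked by expressed genes on both sides (type 1, default 0.40), one
  side (type 2, 0.35) or neither (non-genic, remainder).
- Two URRs (400 kb at |RFD| = 0.9, polarity alternating along the
  chromosome) and two NRRs (700 kb at RFD = 0).
- The noise-free RFD is a sum of logistic transitions: each zone
  contributes an ascending step of height $2e$ with scale width/6, so
  the profile rises from $-e$ to $+e$ across it; termination is a
  single central descending step between nearby zones or, when zones
  are more than 600 kb apart, a pair of descending steps through an
  intermediate plateau at |0.3| so that plateaus of high-efficiency
  zones never extend past the 300-kb URR minimum. The polarity of
  these intermediate plateaus and of the URRs alternates so the
  genome-wide mean RFD stays near 0 - the fork-balance invariant any
  real genome satisfies, and the property the shuffling null leans on.
  URRs and NRRs carry constant guard shoulders (120 kb at |0.5| and
  0.3 respectively) so the constant-RFD calls match the planted spans
  to the bin; zone-free stretches between constant features bridge
  unequal shoulder levels through short laddered plateaus. By
  construction no junction anywhere in the profile ascends by more
  than 0.4, below the 0.5 shift filter, so segment detection sees no
  spurious initiation zones.
- Replication timing is a two-level field (+2.5 within 400 kb of
  gene-flanked zones, -3 elsewhere) smoothed with a 150-kb Gaussian
  plus a small deterministic undulation (amplitude 0.15, period
  1.3 Mb): real timing tracks are never exactly flat, and the
  undulation keeps the timing distribution continuous for decile
  binning while staying clear of the 1.6/-2.0 domain thresholds.
- Genes: expressed flanking genes (35-70 kb, 3-12 kb from the zone
  border) realise the zone types; background genes (15-80 kb, 16-kb
  isolation so most qualify for metagene analyses) receive
  zero-inflated log-normal expression. TPMs are scaled to sum to 1e6
  and read counts drawn as Poisson around TPM x length, so the TPM
  computation is exercised end to end.
- H4K20me3 marks cover half of the non-genic (late) zones and three
  50-kb sub-intervals per NRR.

OK-seq measurement is Poisson-binomial: per bin, total fragments
$N \sim \mathrm{Pois}(\mathrm{depth})$ and reverse-strand reads
$R \sim \mathrm{Binom}(N, (1+\mathrm{RFD})/2)$. The default depth of
100 fragments per 1-kb bin corresponds to a deeply sequenced
experiment and makes the standard-error claims of the aggregate
analyses directly testable. ChIP counts are Poisson with rate
depth x accessibility x enrichment, where enrichment multiplies a
timing ramp interpolating the configured early/late ratio (saturating
at the domain thresholds -2.0 and 1.6, so domain-restricted means
recover the configured ratio exactly in expectation), a gene-body
depletion on actively transcribed genes, a Gaussian TSS peak (sd 2 kb)
at active TSSs, and a boost inside H4K20me3-marked intervals; the
input carries accessibility only (elevated in early-replicating and
TSS-proximal chromatin, which the input division then removes). The
default enrichment parameters (early/late ratios 1.40/1.47/1.15/1.19
for Orc2/Orc3/Mcm3/Mcm7 in G1, flattened MCM ratios in S-G2-M,
gene-body depletions 0.8/0.6/0.7, TSS amplitudes 2.0 for ORC and 1.3
for MCM) mirror the magnitudes reported for pre-replicative-complex
ChIP in human lymphoblastoid cells.

What the generator does *not* emulate: mappability and GC bias, PCR
duplicates, copy-number variation, fragment-length effects, isoform
structure (genes are single-exon), chromosome-scale timing waves, and
correlated noise between factors. Passing the recovery tests therefore
shows the analysis chain is correct and calibrated under a faithful
noise model, not that it is robust to every artefact of real
libraries; the dual with/without-input analyses and the robust
amplitude threshold are the main guards carried over to real data.

Determinism: all randomness flows from the config seed through named
substreams, so identical configs give bit-identical genomes, tracks
and pipeline outputs regardless of call order.

# Numerical choices

- Coordinates are 0-based half-open everywhere, including on disk;
  text output uses 6 significant digits and round-trips exactly at
  that precision.
- Missing data is `NA`, never 0, and propagates through arithmetic;
  bins without coverage stay missing.
- Before convolution, missing runs of up to 10 bins are linearly
  interpolated; longer gaps stay missing and split the detection
  domain, so extrema are never fabricated across large holes.
- The auto amplitude threshold is floored at 1e-3 of the maximum
  absolute convexity: on noise-free profiles the MAD collapses to
  machine precision and floating-point ripples would otherwise qualify
  as extrema.
- The decile histogram nudges duplicated timing-decile breaks apart by
  1e-9 of the range; tied mass lands in the lowest tied column and
  later tied columns are reported as empty rather than failing.
- Aggregate-profile anchors need not be bin-aligned; each queried
  position reads the bin containing it.
- Segment borders are placed at convexity extremum bins (not zero
  crossings), the reading consistent with extrema bounding the
  segment.

# Validation scale

The test suite and the acceptance script run the full chain on one
50-Mb chromosome (segmentation and shuffling), a 30-Mb genome (ChIP
parameter recovery and decile histograms) and a 20-Mb genome (the
structure-free control), with 1e4 null simulations for the Welch
calibration, 3e3 for the ANOVA uniformity check and 1e4 shuffling
draws for the uniformity test - sizes chosen so every stochastic check
has comfortable statistical resolution while the whole validation
completes in minutes on one core.

# Known limitations

- URR/NRR calling applies per-bin thresholds without smoothing and so
  needs pooled, deep profiles; at moderate depth the runs fragment.
- The AS/DS caller assumes shifts are separated by more than about one
  smoothing bandwidth; initiation zones closer than ~2 sigma merge
  into single segments by construction of the convexity method.
- Reads are assigned to bins by their 5' position in the real-data
  adapter; no 200-bp extension is applied, which matters only below
  the 1-kb bin scale.
- The early/late enrichment recovered from the full synthetic
  conditions sits ~0.04 below the configured ratio because marked
  late-replicating intervals carry an additional licensing boost -
  the same coupling expected in real chromatin, and a reminder that
  Table-style ratios fold together several overlapping effects.
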