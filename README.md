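# repliseg

Analysis of the mammalian DNA replication program from binned sequencing
signals: replication fork directionality (RFD) from strand-oriented
Okazaki-fragment sequencing (OK-seq), detection of replication initiation
and termination zones, constant-fork-direction regions, replication
timing domains, and normalisation and classification of
licensing-factor (ORC/MCM) ChIP-seq signal by transcription and
replication timing.

The package is aimed at genomicists who work with OK-seq, Repli-seq,
RNA-seq and ChIP-seq bin counts and want a tested, deterministic
implementation of this analysis chain, together with a synthetic-genome
generator that plants a known replication architecture so every stage
can be validated against ground truth.

## The model

OK-seq counts Okazaki fragments mapping to the reverse (`R`) and forward
(`F`) strand per fixed-width bin. The fork directionality is

    RFD = (R - F) / (R + F)  in [-1, 1]

Ascending segments (ASs) of the RFD profile are initiation zones;
descending segments (DSs) are termination zones. ASs and DSs are
delineated from the convexity of the profile, i.e. its convolution with
the second derivative of a Gaussian (sigma = 32 kb): an immediately
adjacent pair of (positive, negative) convexity extrema of large
amplitude bounds one AS, a (negative, positive) pair one DS. Each
segment carries the RFD shift

    dRFD = RFD(pos_3') - RFD(pos_5')

estimated as the difference of the mean RFD over one sigma outside each
border; efficient initiation zones are those with length > 20 kb and
dRFD > 0.5. Unidirectionally replicating regions (URRs) are runs of
|RFD| > 0.8 over at least 300 kb; null-RFD regions (NRRs) runs of
|RFD| < 0.15 over at least 500 kb. Replication timing domains (RTDs)
come from log2(Early/Late) Repli-seq tracks smoothed over 100 kb, with
early > 1.6 and late < -2.0.

ChIP-seq bin counts are replicate-summed, scaled to genome mean 1, and
divided by the mean-scaled input ("relative read frequency"); gene
expression is quantified as TPM = 1e6 (n_j/l_j) / sum_i(n_i/l_i) with
activity classes no/low/mid/high at 3/10/40. Aggregate profiles report
mean +/- 2 SEM with input division after averaging; distribution
comparisons use the two-sample Kolmogorov-Smirnov statistic with
sample-size correction Z = D sqrt(nm/(n+m)), one-sided Welch t-tests,
and one-way ANOVA with Tukey HSD. Interval-shuffling null models keep
per-chromosome interval counts and lengths fixed while avoiding
assembly gaps (runs of more than 20 Ns).

## Worked example

Simulate a 50-Mb genome with 30 planted initiation zones, measure
OK-seq, and recover the replication program:

```r
library(repliseg)

cfg    <- sim_config(seed = 7)        # 50 Mb, 30 IZs, depth 100/kb-bin
genome <- build_genome(cfg)
ok     <- simulate_okseq(genome$truth)
rfd    <- compute_rfd(ok)

cs  <- convexity_settings()           # sigma = 32 kb, auto threshold
seg <- detect_segments(smooth_convexity(rfd, cs), rfd, cs)
izs <- filter_segments(seg$AS)        # length > 20 kb, dRFD > 0.5
nrow(izs)
#> [1] 30

table(classify_as(izs, genome$genes)$as_type)
#> non_genic     type1     type2
#>         8        12        10

report <- recovery_report(izs, genome$truth)
sprintf("precision %.2f, recall (e >= 0.5) %.2f, mean |dRFD| error %.3f",
        report$precision, report$recall_strong,
        report$mean_delta_rfd_error)
#> [1] "precision 1.00, recall (e >= 0.5) 1.00, mean |dRFD| error 0.017"
```

All 30 detected ascending segments match planted initiation zones:
midpoints land within one smoothing bandwidth of the planted centres
and the measured RFD shift reproduces the planted efficiency (shift =
2e) to ~0.02. On the noise-free profile the constant-RFD and timing
calls match the planted architecture exactly:

```r
rfd0 <- true_rfd(genome$truth)
urr  <- detect_constant_rfd(rfd0, "URR")
nrr  <- detect_constant_rfd(rfd0, "NRR")
sprintf("%d URRs (mean %.0f kb), %d NRRs (mean %.0f kb)",
        nrow(urr), mean(urr$end - urr$start) / 1000,
        nrow(nrr), mean(nrr$end - nrr$start) / 1000)
#> [1] "2 URRs (mean 400 kb), 2 NRRs (mean 700 kb)"

rtds <- detect_rtds(smooth_rt(genome$truth$rt))
sprintf("%d early RTDs, %d late RTDs", nrow(rtds$early), nrow(rtds$late))
#> [1] "17 early RTDs, 14 late RTDs"
```

`run_pipeline(cfg, outdir)` executes the full chain (simulation, RFD,
segmentation, constant-RFD and RTD calls, ChIP normalisation, TPM,
window categorisation, AS classification, region means, recovery
report) and writes every intermediate plus a JSON manifest; identical
configs reproduce byte-identical outputs.

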