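# Transcription quantification and gene-relative window categorisation:
# TPM from per-gene read counts and exonic lengths, expression classes at
# the 3 / 10 / 40 TPM cutoffs, and the 10-kb window categories used for
# the timing-decile histograms.

#' Compute transcripts per kilobase per million (TPM)
#'
#' `TPM_j = 1e6 * (n_j / l_j) / sum_i (n_i / l_i)`, where `n_i` is the
#' read count of gene i and `l_i` its exonic length in kb. TPM values sum
#' to 1e6 over the sample and are invariant under rescaling the library.
#'
#' @param read_counts Non-negative integer read counts per gene.
#' @param exonic_lengths_kb Positive exonic lengths in kb.
#' @return Numeric TPM vector in the input gene order.
#' @export
compute_tpm <- function(read_counts, exonic_lengths_kb) {
  fail_unless(length(read_counts) == length(exonic_lengths_kb),
              "counts and lengths differ in length")
  fail_unless(all(exonic_lengths_kb > 0), "exonic lengths must be positive")
  fail_unless(all(read_counts >= 0), "read counts must be non-negative")
  fail_unless(sum(read_counts) > 0, "all-zero read counts")
  rate <- read_counts / exonic_lengths_kb
  1e6 * rate / sum(rate)
}

#' Classify gene expression from TPM
#'
#' Classes `no` (TPM < 3), `low` (3-10), `mid` (10-40), `high` (> 40);
#' intervals are half-open and lower-inclusive, so TPM 3, 10 and 40 fall
#' into `low`, `mid` and `high` respectively.
#'
#' @param tpm Non-negative TPM values.
#' @return Factor with levels `no`, `low`, `mid`, `high`.
#' @export
classify_expression <- function(tpm) {
  fail_unless(all(tpm >= 0, na.rm = TRUE), "negative TPM")
  cut(tpm, breaks = c(-Inf, 3, 10, 40, Inf), right = FALSE,
      labels = c("no", "low", "mid", "high"))
}

#' Categorise fixed-width windows by transcriptional context
#'
#' Each window (default 10 kb) is labelled `intergenic` when every
#' annotated gene is more than `intergenic_dist` bp away, `silent_body` /
#' `expressed_body` when the window lies fully inside a gene with
#' TPM < 3 / > 3 at more than `body_margin` bp from both gene borders,
#' and `excluded` otherwise (in particular TSS/TTS-proximal windows and
#' windows spanning conflicting gene bodies).
#'
#' @param genes Gene table with `chrom`, `start`, `end`, `tpm`.
#' @param bin_width Window width in bp (default 10000).
#' @param chrom_sizes Named chromosome sizes.
#' @param intergenic_dist Minimal distance to any gene for `intergenic`
#'   (default 5000, exclusive).
#' @param body_margin Minimal distance from gene borders for body windows
#'   (default 3000, exclusive).
#' @return Named list of factor vectors (one per chromosome) with levels
#'   `intergenic`, `silent_body`, `expressed_body`, `excluded`.
#' @export
categorize_windows <- function(genes, bin_width = 10000, chrom_sizes,
                               intergenic_dist = 5000, body_margin = 3000) {
  lv <- c("intergenic", "silent_body", "expressed_body", "excluded")
  out <- list()
  for (ch in names(chrom_sizes)) {
    nb <- n_bins(chrom_sizes[[ch]], bin_width)
    ws <- (seq_len(nb) - 1) * bin_width
    we <- pmin(ws + bin_width, chrom_sizes[[ch]])
    cat <- rep("excluded", nb)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) {
      cat[] <- "intergenic"
    } else {
      gr <- iranges0(g$start, g$end)
      wr <- iranges0(ws, we)
      # intergenic: every gene strictly more than intergenic_dist away
      # (extension by dist + 1 makes a gap of exactly dist disqualify)
      near <- IRanges::overlapsAny(
        wr, iranges0(pmax(g$start - intergenic_dist - 1, 0),
                     g$end + intergenic_dist + 1))
      cat[!near] <- "intergenic"
      # body windows: strictly more than body_margin inside the gene,
      # i.e. window start - gene start > margin and gene end - window
      # end > margin
      core_ok <- (g$end - g$start) > 2 * body_margin + 2
      if (any(core_ok)) {
        core <- iranges0(g$start[core_ok] + body_margin + 1,
                         g$end[core_ok] - body_margin - 1)
        hits <- IRanges::findOverlaps(wr, core, type = "within")
        if (length(hits)) {
          qi <- S4Vectors_queryHits(hits)
          si <- S4Vectors_subjectHits(hits)
          tpm <- g$tpm[core_ok][si]
          lab <- ifelse(tpm < 3, "silent_body",
                        ifelse(tpm > 3, "expressed_body", "excluded"))
          agg <- tapply(lab, qi, function(x) {
            u <- unique(x)
            if (length(u) == 1) u else "excluded"
          })
          cat[as.integer(names(agg))] <- as.character(agg)
        }
      }
    }
    out[[ch]] <- factor(cat, levels = lv)
  }
  out
}

S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)
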