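# End-to-end orchestration: simulate a genome, run every analysis stage
# in order, write all intermediates plus a manifest, and score detected
# segments against the planted truth.

#' Match detected ascending segments against planted initiation zones
#'
#' A detected AS matches a planted IZ when its midpoint lies within
#' `tolerance` bp of the IZ centre. Reports precision (fraction of
#' detected ASs matching any planted IZ), recall overall and for IZs with
#' efficiency at least `min_eff`, the mean absolute error of the RFD
#' shift against the planted `2 e`, the midpoint error, and the number of
#' AS calls lying inside planted URRs.
#'
#' @param detected_as A [segment_table()] of ascending segments.
#' @param truth A `SyntheticTruth`.
#' @param tolerance Midpoint matching tolerance in bp (default 32000).
#' @param min_eff Efficiency cutoff for the headline recall (default 0.5).
#' @return A list of scores.
#' @export
recovery_report <- function(detected_as, truth, tolerance = 32000,
                            min_eff = 0.5) {
  iz <- truth$segments[truth$segments$kind == "IZ", , drop = FALSE]
  urr <- truth$segments[truth$segments$kind == "URR", , drop = FALSE]
  n_det <- nrow(detected_as)
  match_iz <- rep(NA_integer_, n_det)
  for (i in seq_len(n_det)) {
    mid <- (detected_as$start[i] + detected_as$end[i]) / 2
    cand <- which(iz$chrom == detected_as$chrom[i])
    if (!length(cand)) next
    d <- abs((iz$start[cand] + iz$end[cand]) / 2 - mid)
    j <- cand[which.min(d)]
    if (min(d) <= tolerance) match_iz[i] <- j
  }
  matched_iz <- unique(match_iz[!is.na(match_iz)])
  recall_all <- if (nrow(iz)) length(matched_iz) / nrow(iz) else NA_real_
  strong <- which(iz$efficiency >= min_eff)
  recall_strong <- if (length(strong))
    length(intersect(matched_iz, strong)) / length(strong) else NA_real_
  precision <- if (n_det) mean(!is.na(match_iz)) else NA_real_
  hit <- !is.na(match_iz)
  delta_err <- midpoint_err <- NA_real_
  if (any(hit)) {
    planted_shift <- 2 * iz$efficiency[match_iz[hit]]
    delta_err <- mean(abs(detected_as$delta_rfd[hit] - planted_shift))
    mids <- (detected_as$start[hit] + detected_as$end[hit]) / 2
    centers <- (iz$start[match_iz[hit]] + iz$end[match_iz[hit]]) / 2
    midpoint_err <- mean(abs(mids - centers))
  }
  in_urr <- 0L
  if (n_det && nrow(urr)) {
    mids <- (detected_as$start + detected_as$end) / 2
    for (i in seq_len(n_det)) {
      sel <- urr$chrom == detected_as$chrom[i] &
        urr$start <= mids[i] & urr$end > mids[i]
      if (any(sel)) in_urr <- in_urr + 1L
    }
  }
  list(n_detected = n_det, n_planted = nrow(iz),
       precision = precision, recall = recall_all,
       recall_strong = recall_strong, mean_delta_rfd_error = delta_err,
       mean_midpoint_error_bp = midpoint_err, as_calls_in_urr = in_urr)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a genome from `config`, then runs in order: OK-seq
#' simulation and RFD computation, convexity segmentation with the
#' default filters, URR/NRR calls, RT smoothing and RTD calls, ChIP
#' simulation and normalisation for the requested factors, TPM and window
#' categorisation, AS classification and H4K20me3 subsetting, early/late
#' region means, and the truth recovery report. All intermediates are
#' written under `outdir` along with a JSON manifest; identical configs
#' produce identical outputs.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param factors ChIP factors to simulate (default Orc2, Mcm3,
#'   H4K20me3).
#' @return Invisibly, a list with every stage's in-memory results.
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("replirun"),
                         factors = c("Orc2", "Mcm3", "H4K20me3")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage) message(sprintf("[repliseg] %s", stage))

  log_stage("simulate")
  gb <- build_genome(config)
  truth <- gb$truth
  write_gene_table(gb$genes, file.path(outdir, "genes.tsv"))
  truth_json <- list(
    chrom_sizes = as.list(truth$chrom_sizes),
    segments = truth$segments, marks = truth$marks,
    seed = config$seed)
  jsonlite::write_json(truth_json, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  log_stage("rfd")
  ok <- simulate_okseq(truth)
  rfd <- compute_rfd(ok)
  write_bedgraph(rfd, file.path(outdir, "rfd.bedgraph"))

  log_stage("segment")
  cs <- convexity_settings()
  conv <- smooth_convexity(rfd, cs)
  seg <- detect_segments(conv, rfd, cs)
  as_kept <- filter_segments(seg$AS)
  ds_kept <- filter_segments(seg$DS, direction = -1)
  write_segments_bed(as_kept, file.path(outdir, "as.bed"))
  write_segments_bed(ds_kept, file.path(outdir, "ds.bed"))

  log_stage("constant-rfd")
  urr <- detect_constant_rfd(rfd, "URR")
  nrr <- detect_constant_rfd(rfd, "NRR")
  write_segments_bed(rbind(urr, nrr), file.path(outdir, "constant_rfd.bed"))

  log_stage("rtd")
  rt_sm <- smooth_rt(truth$rt)
  rtds <- detect_rtds(rt_sm)
  write_segments_bed(rbind(rtds$early, rtds$late),
                     file.path(outdir, "rtd.bed"))

  log_stage("chip-norm")
  input_counts <- simulate_chip(truth, "input")
  chip <- list()
  for (f in factors) {
    counts <- simulate_chip(truth, f)
    rel <- chip_relative_frequency(list(counts), input_counts)
    chip[[f]] <- rel
    write_bedgraph(rebin_counts(counts, config$rt_bin_width),
                   file.path(outdir, sprintf("chip_%s_counts.bedgraph", f)))
  }

  log_stage("tpm")
  genes <- gb$genes
  genes$tpm_recomputed <- compute_tpm(genes$read_count,
                                      genes$exonic_length_kb)
  genes$activity_class <- as.character(classify_expression(genes$tpm))
  write_gene_table(genes, file.path(outdir, "genes_tpm.tsv"))
  categories <- categorize_windows(genes, config$rt_bin_width,
                                   truth$chrom_sizes)

  log_stage("classify-as")
  as_classified <- classify_as(as_kept, genes)
  write_segments_bed(as_classified, file.path(outdir, "as_classified.bed"))
  mark_subsets <- NULL
  if ("H4K20me3" %in% names(chip)) {
    ng <- as_classified[as_classified$as_type %in% "non_genic", ,
                        drop = FALSE]
    if (nrow(ng)) {
      mark_subsets <- subset_by_mark(
        ng, rebin_relative(chip[["H4K20me3"]], config$rt_bin_width))
    }
  }

  log_stage("region-means")
  region_means <- NULL
  if (length(chip) && nrow(rtds$early) && nrow(rtds$late)) {
    region_means <- lapply(chip, function(track) {
      region_mean_frequency(list(early = rtds$early, late = rtds$late),
                            rebin_relative(track, config$rt_bin_width),
                            genes = genes)
    })
  }

  log_stage("recovery")
  report <- recovery_report(as_kept, truth)
  manifest <- list(
    seed = config$seed,
    bin_width = config$bin_width,
    rt_bin_width = config$rt_bin_width,
    chrom_sizes = as.list(truth$chrom_sizes),
    factors = factors,
    stages = c("simulate", "rfd", "segment", "constant-rfd", "rtd",
               "chip-norm", "tpm", "classify-as", "region-means",
               "recovery"),
    outputs = list.files(outdir),
    recovery = report)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(truth = truth, rfd = rfd, segments = seg,
                 as_kept = as_kept, ds_kept = ds_kept, urr = urr,
                 nrr = nrr, rtds = rtds, chip = chip, genes = genes,
                 categories = categories, as_classified = as_classified,
                 mark_subsets = mark_subsets, region_means = region_means,
                 recovery = report, outdir = outdir))
}

#' Average a relative-frequency track into coarser bins
#'
#' Means (not sums) of the fine bins per coarse bin, NA-aware; used to
#' carry 1-kb relative frequencies into 10-kb analyses.
#'
#' @param track A [binned_track()].
#' @param new_width Target bin width, a multiple of the current width.
#' @return A [binned_track()] at `new_width`.
#' @export
rebin_relative <- function(track, new_width) {
  w <- track$bin_width
  fail_unless(new_width %% w == 0, "new_width must be a multiple")
  k <- new_width %/% w
  vals <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    nb <- n_bins(track$chrom_sizes[[ch]], new_width)
    grp <- rep(seq_len(nb), each = k)[seq_along(v)]
    as.numeric(tapply(v, grp, function(z) {
      if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
    }))
  })
  names(vals) <- names(track$values)
  binned_track(vals, new_width, track$chrom_sizes)
}
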