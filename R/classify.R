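# Classification of ascending segments by transcriptional context, mark
# based interval subsetting, replicate peak intersection, and per-class
# region means of relative read frequency.

#' Classify ascending segments by flanking transcription
#'
#' An AS is `non_genic` when the segment extended by `flank` bp on both
#' sides overlaps no annotated gene (regardless of expression); otherwise
#' it is genic. Genic ASs are `type1` when both borders lie within
#' `flank` bp of an expressed gene body (TPM > `tpm_threshold`), `type2`
#' when exactly one border qualifies (with `orientation_flipped = TRUE`
#' when the qualifying border is the left one, so mirrored segments have
#' their expressed-gene border on the right), and `genic_other` otherwise.
#'
#' @param as_segments A [segment_table()] of ascending segments.
#' @param genes Gene table with `chrom`, `start`, `end`, `tpm`.
#' @param tpm_threshold Expression cutoff (default 3, exclusive).
#' @param flank Border distance in bp (default 20000, exclusive).
#' @return The segment table with `as_type` and `orientation_flipped`
#'   filled in.
#' @export
classify_as <- function(as_segments, genes, tpm_threshold = 3,
                        flank = 20000) {
  if (!nrow(as_segments)) return(as_segments)
  out <- as_segments
  expressed <- genes[genes$tpm > tpm_threshold, , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    ch <- out$chrom[i]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    ext_lo <- max(out$start[i] - flank, 0)
    ext_hi <- out$end[i] + flank
    genic <- nrow(g) > 0 &&
      any(g$start < ext_hi & g$end > ext_lo)
    if (!genic) {
      out$as_type[i] <- "non_genic"
      next
    }
    e <- expressed[expressed$chrom == ch, , drop = FALSE]
    border_hit <- function(pos) {
      if (!nrow(e)) return(FALSE)
      d <- ifelse(e$end <= pos, pos - e$end,
                  ifelse(e$start >= pos, e$start - pos, 0))
      any(d < flank)
    }
    left <- border_hit(out$start[i])
    right <- border_hit(out$end[i])
    if (left && right) {
      out$as_type[i] <- "type1"
    } else if (left || right) {
      out$as_type[i] <- "type2"
      out$orientation_flipped[i] <- left && !right
    } else {
      out$as_type[i] <- "genic_other"
    }
  }
  out
}

#' Subset intervals by a mark's relative read frequency
#'
#' Computes the genome mean and SD of the mark track over all non-missing
#' bins, then per interval the mean mark over overlapping bins: intervals
#' with mean above `mean + 1.5 sd` are `high`, below the mean are `low`,
#' the rest `neither`. The three sets partition the input.
#'
#' @param intervals A [segment_table()] or [interval_set()].
#' @param mark_track Relative read frequency [binned_track()].
#' @param sd_multiple High cutoff in SDs above the mean (default 1.5).
#' @param stat_bins Optional logical list (per chromosome) restricting the
#'   bins over which the genome mean/SD are estimated (e.g. fully
#'   intergenic windows); all non-missing bins when `NULL`.
#' @return A list with data frames `high`, `low`, `neither`, each carrying
#'   an extra `mark_mean` column, plus the genome `mean` and `sd`.
#' @export
subset_by_mark <- function(intervals, mark_track, sd_multiple = 1.5,
                           stat_bins = NULL) {
  if (is.null(stat_bins)) {
    v <- track_values(mark_track)
  } else {
    v <- unlist(Map(function(x, keep) x[keep], mark_track$values,
                    stat_bins[names(mark_track$values)]),
                use.names = FALSE)
  }
  mu <- mean(v, na.rm = TRUE)
  s <- stats::sd(v, na.rm = TRUE)
  w <- mark_track$bin_width
  m <- rep(NA_real_, nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    tv <- mark_track$values[[intervals$chrom[i]]]
    if (is.null(tv)) next
    b0 <- intervals$start[i] %/% w + 1L
    b1 <- min(ceiling(intervals$end[i] / w), length(tv))
    x <- tv[b0:b1]
    if (all(is.na(x))) {
      warning(sprintf("interval %s:%d-%d has no covered bins",
                      intervals$chrom[i], intervals$start[i],
                      intervals$end[i]))
    } else {
      m[i] <- mean(x, na.rm = TRUE)
    }
  }
  intervals$mark_mean <- m
  is_high <- !is.na(m) & m > mu + sd_multiple * s
  is_low <- !is.na(m) & m < mu
  list(high = intervals[is_high, , drop = FALSE],
       low = intervals[is_low, , drop = FALSE],
       neither = intervals[!is_high & !is_low, , drop = FALSE],
       mean = mu, sd = s)
}

#' Intersect replicate peak sets
#'
#' Retains the merged peaks of the first set that overlap (by at least
#' 1 bp) a peak in every other set; the result is the union-merge of the
#' retained first-set peaks.
#'
#' @param peak_sets List of at least two [interval_set()]s.
#' @return An [interval_set()].
#' @export
intersect_replicate_peaks <- function(peak_sets) {
  fail_unless(length(peak_sets) >= 2, "need at least two peak sets")
  if (any(vapply(peak_sets, nrow, integer(1)) == 0)) return(interval_set())
  first <- peak_sets[[1]]
  # union-merge of the first set
  merged <- list()
  for (ch in unique(first$chrom)) {
    f <- first[first$chrom == ch, , drop = FALSE]
    red <- IRanges::reduce(iranges0(f$start, f$end))
    merged[[ch]] <- interval_set(rep(ch, length(red)),
                                 IRanges::start(red) - 1L,
                                 IRanges::end(red))
  }
  merged <- do.call(rbind, merged)
  keep <- rep(TRUE, nrow(merged))
  for (other in peak_sets[-1]) {
    keep <- keep & overlaps_any(merged, other)
  }
  out <- merged[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean relative read frequency per interval class
#'
#' Drops bins overlapping any gene extended by `gene_flank` bp, then for
#' each interval class reports the mean, SEM and bin count of the track
#' over bins lying fully inside the class intervals, plus the ratio of
#' the first class mean to each other class mean.
#'
#' @param classes Named list of interval data frames (e.g.
#'   `list(early = ..., late = ...)`).
#' @param track Relative read frequency [binned_track()] (10-kb bins).
#' @param genes Optional gene table for the exclusion zone.
#' @param gene_flank Gene exclusion flank in bp (default 10000).
#' @return A data frame with one row per class (`class`, `mean`, `sem`,
#'   `n_bins`, `ratio_to_first`).
#' @export
region_mean_frequency <- function(classes, track, genes = NULL,
                                  gene_flank = 10000) {
  w <- track$bin_width
  excl <- NULL
  if (!is.null(genes) && nrow(genes)) {
    excl <- interval_set(genes$chrom, pmax(genes$start - gene_flank, 0),
                         genes$end + gene_flank)
  }
  stats_one <- function(iv) {
    vals <- numeric(0)
    for (ch in unique(iv$chrom)) {
      tv <- track$values[[ch]]
      if (is.null(tv)) next
      sel <- iv[iv$chrom == ch, , drop = FALSE]
      nb <- length(tv)
      starts <- (seq_len(nb) - 1) * w
      bins_in <- IRanges::overlapsAny(
        iranges0(starts, starts + w),
        iranges0(sel$start, sel$end), type = "within")
      if (!is.null(excl)) {
        ex <- excl[excl$chrom == ch, , drop = FALSE]
        if (nrow(ex)) {
          bins_in <- bins_in & !IRanges::overlapsAny(
            iranges0(starts, starts + w), iranges0(ex$start, ex$end))
        }
      }
      vals <- c(vals, tv[bins_in])
    }
    vals <- vals[!is.na(vals)]
    fail_unless(length(vals) > 0, "a class has no qualifying bins")
    c(mean = mean(vals), sem = stats::sd(vals) / sqrt(length(vals)),
      n = length(vals))
  }
  res <- t(vapply(classes, stats_one, numeric(3)))
  data.frame(class = names(classes), mean = res[, "mean"],
             sem = res[, "sem"], n_bins = as.integer(res[, "n"]),
             ratio_to_first = res[1, "mean"] / res[, "mean"],
             row.names = NULL, stringsAsFactors = FALSE)
}
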