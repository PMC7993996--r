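# Locus-aligned aggregate profiles (segment borders, TSS/TTS metagenes),
# replication-timing decile 2D histograms, and the statistical tests used
# to compare read-frequency distributions.

# Extract a window of per-bin values around an anchor, in orientation
# ("+" keeps genomic order, "-" mirrors). offsets are bin starts relative
# to the anchor; anchors need not be bin-aligned (each queried position
# reads the bin containing it). Bins outside the chromosome are NA.
extract_window <- function(track_vec, w, anchor, offsets, orient = "+") {
  if (orient == "+") {
    pos <- anchor + offsets
  } else {
    pos <- anchor - offsets - w
  }
  idx <- pos %/% w + 1L
  ok <- idx >= 1 & idx <= length(track_vec)
  out <- rep(NA_real_, length(offsets))
  out[ok] <- track_vec[idx[ok]]
  out
}

#' Aggregate ChIP profile at segment borders
#'
#' Aligns segments on their left (5') or right (3') borders and averages
#' mean-normalised sample and input tracks across loci per 1-kb offset,
#' from `upstream` bp outside the segment to `inside` bp within it.
#' Input normalisation is performed after averaging: the reported profile
#' is `mean(sample) / mean(input)` per offset, with a +/- 2 SEM band
#' propagated from the sample track. Segments flagged
#' `orientation_flipped` are mirrored (their 5' border is treated as the
#' 3' one) when `respect_orientation` is `TRUE`.
#'
#' @param segments A [segment_table()].
#' @param sample_track Mean-normalised (not input-divided) 1-kb track.
#' @param input_track Mean-normalised input 1-kb track, or `NULL` to skip
#'   input division.
#' @param align `"5p"` or `"3p"`.
#' @param upstream Bp outside the border (default 50000).
#' @param inside Bp inside the border (default 10000).
#' @param respect_orientation Mirror flipped segments (default TRUE).
#' @return A data frame with `offset` (bp relative to the border, negative
#'   outside), `profile`, `lo`, `hi`, `mean_sample`, `sem_sample`,
#'   `mean_input`, `n`, plus an attribute `n_skipped` counting segments
#'   shorter than `2 * inside`.
#' @export
border_profile <- function(segments, sample_track, input_track = NULL,
                           align = c("5p", "3p"), upstream = 50000,
                           inside = 10000, respect_orientation = TRUE) {
  align <- match.arg(align)
  w <- sample_track$bin_width
  if (!is.null(input_track)) check_geometry(sample_track, input_track)
  offsets <- seq(-upstream, inside - w, by = w)
  keep <- (segments$end - segments$start) >= 2 * inside
  n_skipped <- sum(!keep)
  segments <- segments[keep, , drop = FALSE]
  smat <- matrix(NA_real_, nrow(segments), length(offsets))
  imat <- smat
  for (i in seq_len(nrow(segments))) {
    flip <- respect_orientation && isTRUE(segments$orientation_flipped[i])
    side <- if (!flip) align else if (align == "5p") "3p" else "5p"
    anchor <- if (side == "5p") segments$start[i] else segments$end[i]
    orient <- if (side == "5p") "+" else "-"
    sv <- sample_track$values[[segments$chrom[i]]]
    smat[i, ] <- extract_window(sv, w, anchor, offsets, orient)
    if (!is.null(input_track)) {
      iv <- input_track$values[[segments$chrom[i]]]
      imat[i, ] <- extract_window(iv, w, anchor, offsets, orient)
    }
  }
  col_mean <- function(m) apply(m, 2, mean, na.rm = TRUE)
  col_sem <- function(m) apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  })
  ms <- col_mean(smat); ss <- col_sem(smat)
  n <- apply(smat, 2, function(x) sum(!is.na(x)))
  if (!is.null(input_track)) {
    mi <- col_mean(imat)
    profile <- ms / mi
    lo <- (ms - 2 * ss) / mi
    hi <- (ms + 2 * ss) / mi
  } else {
    mi <- rep(NA_real_, length(ms))
    profile <- ms; lo <- ms - 2 * ss; hi <- ms + 2 * ss
  }
  out <- data.frame(offset = offsets, profile = profile, lo = lo, hi = hi,
                    mean_sample = ms, sem_sample = ss, mean_input = mi,
                    n = n)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' TSS/TTS metagene profiles by expression class
#'
#' Eligible genes are strictly longer than `min_length` with no other gene
#' within `isolation` bp. Profiles are oriented 5' to 3' by gene strand in
#' a window of `window` bp centred on the TSS or TTS, averaged per
#' expression class with input division after averaging.
#'
#' @param genes Gene table with `chrom`, `start`, `end`, `strand`, `tpm`.
#' @param sample_track Mean-normalised 1-kb track.
#' @param input_track Mean-normalised input track or `NULL`.
#' @param align `"TSS"` or `"TTS"`.
#' @param min_length Minimal gene length in bp (default 30000, exclusive).
#' @param isolation Required gene-free flank in bp (default 15000).
#' @param window Window width in bp centred on the anchor (default 30000).
#' @return Named list (one element per non-empty expression class) of
#'   data frames as in [border_profile()], `offset` being the distance
#'   from the anchor in the gene's reading direction.
#' @export
gene_metaprofile <- function(genes, sample_track, input_track = NULL,
                             align = c("TSS", "TTS"), min_length = 30000,
                             isolation = 15000, window = 30000) {
  align <- match.arg(align)
  w <- sample_track$bin_width
  offsets <- seq(-window / 2, window / 2 - w, by = w)
  long_enough <- (genes$end - genes$start) > min_length
  # a gene always overlaps its own flank window, so count hits
  isolated <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[genes$chrom == genes$chrom[i], , drop = FALSE]
    lo <- genes$start[i] - isolation
    hi <- genes$end[i] + isolation
    sum(g$start < hi & g$end > lo) == 1
  }, logical(1))
  eligible <- genes[long_enough & isolated, , drop = FALSE]
  eligible$class <- classify_expression(eligible$tpm)
  out <- list()
  for (cl in levels(eligible$class)) {
    sel <- eligible[eligible$class == cl, , drop = FALSE]
    if (!nrow(sel)) {
      warning(sprintf("no eligible genes in class %s", cl))
      next
    }
    smat <- matrix(NA_real_, nrow(sel), length(offsets))
    imat <- smat
    for (i in seq_len(nrow(sel))) {
      plus <- sel$strand[i] != "-"
      anchor <- if (align == "TSS") {
        if (plus) sel$start[i] else sel$end[i]
      } else {
        if (plus) sel$end[i] else sel$start[i]
      }
      sv <- sample_track$values[[sel$chrom[i]]]
      smat[i, ] <- extract_window(sv, w, anchor, offsets,
                                  if (plus) "+" else "-")
      if (!is.null(input_track)) {
        iv <- input_track$values[[sel$chrom[i]]]
        imat[i, ] <- extract_window(iv, w, anchor, offsets,
                                    if (plus) "+" else "-")
      }
    }
    ms <- apply(smat, 2, mean, na.rm = TRUE)
    ss <- apply(smat, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) return(NA_real_)
      stats::sd(x) / sqrt(length(x))
    })
    if (!is.null(input_track)) {
      mi <- apply(imat, 2, mean, na.rm = TRUE)
      prof <- ms / mi; lo <- (ms - 2 * ss) / mi; hi <- (ms + 2 * ss) / mi
    } else {
      mi <- rep(NA_real_, length(ms))
      prof <- ms; lo <- ms - 2 * ss; hi <- ms + 2 * ss
    }
    out[[cl]] <- data.frame(offset = offsets, profile = prof, lo = lo,
                            hi = hi, mean_sample = ms, sem_sample = ss,
                            mean_input = mi,
                            n = apply(smat, 2, function(x) sum(!is.na(x))))
  }
  out
}

#' Replication-timing decile 2D histogram of ChIP frequencies
#'
#' Bins the genome-wide smoothed timing distribution into deciles and, per
#' decile column, estimates the probability distribution of ChIP relative
#' read frequencies over the selected 10-kb windows (columns sum to 1).
#' The frequency axis uses `n_freq_bins` equal bins on \[0, P99.5\] plus
#' an overflow bin.
#'
#' @param chip_track 10-kb relative read frequency [binned_track()].
#' @param rt_smoothed 10-kb smoothed timing [binned_track()].
#' @param categories Output of [categorize_windows()]; only windows of
#'   `category` enter the histogram.
#' @param category One of `"intergenic"`, `"silent_body"`,
#'   `"expressed_body"`, or `"all"`.
#' @param restriction Optional interval data frame; only windows fully
#'   inside these intervals are used (e.g. AS, DS, URR or NRR calls).
#' @param n_freq_bins Number of ChIP-frequency bins (default 50).
#' @return A list with the column-normalised `matrix`
#'   (frequency bins x 10 deciles), `freq_breaks`, `rt_breaks`,
#'   per-column `stats` (n, mean, median, quartiles, deciles) and the
#'   total window count `n`.
#' @export
rt_decile_hist2d <- function(chip_track, rt_smoothed, categories = NULL,
                             category = "all", restriction = NULL,
                             n_freq_bins = 50) {
  check_geometry(chip_track, rt_smoothed)
  w <- chip_track$bin_width
  rt_all <- track_values(rt_smoothed)
  rt_breaks <- stats::quantile(rt_all, probs = seq(0, 1, 0.1), na.rm = TRUE)
  rt_breaks[1] <- -Inf; rt_breaks[11] <- Inf
  # heavy ties can duplicate decile breaks; nudge them apart so the cut
  # stays well-defined (tied mass lands in the lowest of the tied
  # columns, later ones come back empty and are reported as missing)
  if (anyDuplicated(rt_breaks)) {
    eps <- 1e-9 * diff(range(rt_all, na.rm = TRUE))
    for (j in 2:10) {
      if (rt_breaks[j] <= rt_breaks[j - 1])
        rt_breaks[j] <- rt_breaks[j - 1] + eps
    }
  }
  chip <- numeric(0); rt <- numeric(0)
  for (ch in names(chip_track$values)) {
    cv <- chip_track$values[[ch]]
    tv <- rt_smoothed$values[[ch]]
    keep <- !is.na(cv) & !is.na(tv)
    if (!is.null(categories) && category != "all") {
      keep <- keep & !is.na(categories[[ch]]) &
        categories[[ch]] == category
    }
    if (!is.null(restriction)) {
      nb <- length(cv)
      starts <- (seq_len(nb) - 1) * w
      sel <- restriction[restriction$chrom == ch, , drop = FALSE]
      inside <- if (nrow(sel)) {
        IRanges::overlapsAny(iranges0(starts, starts + w),
                             iranges0(sel$start, sel$end),
                             type = "within")
      } else rep(FALSE, nb)
      keep <- keep & inside
    }
    chip <- c(chip, cv[keep]); rt <- c(rt, tv[keep])
  }
  hi <- stats::quantile(chip, 0.995, na.rm = TRUE)
  if (!is.finite(hi) || hi <= 0) hi <- max(chip, 1)
  freq_breaks <- c(seq(0, hi, length.out = n_freq_bins + 1), Inf)
  col <- cut(rt, rt_breaks, labels = FALSE, include.lowest = TRUE)
  row <- cut(chip, freq_breaks, labels = FALSE, include.lowest = TRUE)
  mat <- matrix(0, n_freq_bins + 1, 10)
  tab <- table(factor(row, levels = seq_len(n_freq_bins + 1)),
               factor(col, levels = 1:10))
  mat[] <- as.numeric(tab)
  csum <- colSums(mat)
  stats_cols <- lapply(1:10, function(j) {
    x <- chip[col == j]
    if (!length(x)) return(rep(NA_real_, 8))
    q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9))
    c(n = length(x), mean = mean(x), d1 = q[[1]], q1 = q[[2]],
      median = q[[3]], q3 = q[[4]], d9 = q[[5]], sd = stats::sd(x))
  })
  stats_df <- as.data.frame(do.call(rbind, stats_cols))
  names(stats_df) <- c("n", "mean", "d1", "q1", "median", "q3", "d9", "sd")
  stats_df$decile <- 1:10
  for (j in which(csum > 0)) mat[, j] <- mat[, j] / csum[j]
  mat[, csum == 0] <- NA_real_
  list(matrix = mat, freq_breaks = freq_breaks, rt_breaks = rt_breaks,
       stats = stats_df, n = length(chip))
}
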