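# Interval-shuffling null model and RFD aggregation around interval sets.
# Shuffling keeps the number and lengths of intervals constant per
# chromosome and avoids masked (unmappable) genome regions.

#' Shuffle intervals within chromosomes avoiding a gap mask
#'
#' Per draw and per chromosome, every interval is reassigned a uniform
#' random start such that the placed interval lies within the chromosome
#' and overlaps no mask region; lengths and per-chromosome counts are
#' preserved exactly. Rejection sampling with a retry cap of 1e4 per
#' interval. Shuffled intervals may overlap one another unless
#' `allow_self_overlap = FALSE`.
#'
#' @param intervals An [interval_set()] (or segment table).
#' @param chrom_sizes Named chromosome sizes in bp.
#' @param gap_mask Optional [interval_set()] of excluded regions (e.g.
#'   from [n_gap_mask()]).
#' @param seed Integer seed.
#' @param n_draws Number of shuffled sets.
#' @param allow_self_overlap Permit overlaps among placed intervals
#'   (default TRUE).
#' @return A list of `n_draws` interval data frames.
#' @export
shuffle_intervals <- function(intervals, chrom_sizes, gap_mask = NULL,
                              seed = 1, n_draws = 1,
                              allow_self_overlap = TRUE) {
  fail_unless(nrow(intervals) > 0, "no intervals to shuffle")
  for (i in seq_len(nrow(intervals))) {
    fail_unless(intervals$end[i] - intervals$start[i] <=
                  chrom_sizes[[intervals$chrom[i]]],
                "interval longer than its chromosome")
  }
  with_seed(seed, {
    lapply(seq_len(n_draws), function(d) {
      out <- intervals
      for (ch in unique(intervals$chrom)) {
        idx <- which(intervals$chrom == ch)
        L <- chrom_sizes[[ch]]
        mk <- if (is.null(gap_mask)) NULL else
          gap_mask[gap_mask$chrom == ch, , drop = FALSE]
        placed_s <- numeric(0); placed_e <- numeric(0)
        for (i in idx) {
          len <- intervals$end[i] - intervals$start[i]
          ok <- FALSE
          for (t in seq_len(10000)) {
            s <- floor(stats::runif(1, 0, L - len + 1))
            if (s > L - len) s <- L - len
            e <- s + len
            if (!is.null(mk) && nrow(mk) &&
                any(mk$start < e & mk$end > s)) next
            if (!allow_self_overlap && length(placed_s) &&
                any(placed_s < e & placed_e > s)) next
            ok <- TRUE
            break
          }
          fail_unless(ok,
                      "cannot place interval %s:%d-%d: mask too dense",
                      ch, intervals$start[i], intervals$end[i])
          out$start[i] <- s; out$end[i] <- e
          placed_s <- c(placed_s, s); placed_e <- c(placed_e, e)
        }
      }
      out
    })
  })
}

#' Aggregate RFD profile centred on intervals
#'
#' Aligns the RFD track on interval centres and reports, per offset, the
#' mean across intervals with a 95% confidence envelope based on the mean
#' and standard deviation at each position (`mean +/- 1.96 sd / sqrt(n)`
#' by default; `band = "sd"` gives `mean +/- 1.96 sd`).
#'
#' @param intervals An [interval_set()].
#' @param rfd A [binned_track()] of RFD (e.g. at 10-kb bins).
#' @param halfwidth Half-width of the window in bp (default 500000).
#' @param band `"se"` (default) or `"sd"`.
#' @return A data frame with `offset`, `mean`, `lo`, `hi`, `n`.
#' @export
aggregate_rfd_at <- function(intervals, rfd, halfwidth = 500000,
                             band = c("se", "sd")) {
  band <- match.arg(band)
  fail_unless(nrow(intervals) > 0, "empty interval set")
  w <- rfd$bin_width
  offsets <- seq(-halfwidth, halfwidth - w, by = w)
  mat <- matrix(NA_real_, nrow(intervals), length(offsets))
  for (i in seq_len(nrow(intervals))) {
    v <- rfd$values[[intervals$chrom[i]]]
    if (is.null(v)) next
    center <- ((intervals$start[i] + intervals$end[i]) / 2) %/% w * w
    mat[i, ] <- extract_window(v, w, center, offsets, "+")
  }
  n <- apply(mat, 2, function(x) sum(!is.na(x)))
  m <- apply(mat, 2, function(x) mean(x, na.rm = TRUE))
  s <- apply(mat, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(0)
    stats::sd(x)
  })
  half <- if (band == "se") 1.96 * s / sqrt(pmax(n, 1)) else 1.96 * s
  data.frame(offset = offsets, mean = m, lo = m - half, hi = m + half,
             n = n)
}
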