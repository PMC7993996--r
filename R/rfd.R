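# Replication fork directionality (RFD) from stranded Okazaki-fragment bin
# counts: RFD = (R - F) / (R + F), where R and F count reads mapped to the
# reverse and forward strand. Replicates are pooled by summing counts; the
# replicate QC correlation follows the 50-kb window, >100 reads rule.

#' Pool stranded-count replicates
#'
#' Element-wise sum of reverse- and forward-strand counts across replicates
#' with identical bin geometry.
#'
#' @param replicates List of [stranded_bin_counts()] objects.
#' @return A pooled [stranded_bin_counts()].
#' @export
pool_replicates <- function(replicates) {
  fail_unless(length(replicates) >= 1, "need at least one replicate")
  out <- replicates[[1]]
  if (length(replicates) == 1) return(out)
  sum_na0 <- function(a, b) {
    a[is.na(a)] <- 0; b[is.na(b)] <- 0; a + b
  }
  Rt <- out$R; Ft <- out$F
  for (rep in replicates[-1]) {
    check_geometry(Rt, rep$R)
    Rt <- track_map2(Rt, rep$R, sum_na0)
    Ft <- track_map2(Ft, rep$F, sum_na0)
  }
  stranded_bin_counts(Rt$values, Ft$values, out$bin_width, out$chrom_sizes)
}

#' Compute replication fork directionality
#'
#' Per bin, `RFD = (R - F) / (R + F)` when `R + F >= min_total`, else
#' missing. Values lie in \[-1, 1\]: +1 when all Okazaki fragments map to
#' the reverse strand (purely rightward-moving forks), -1 when all map to
#' the forward strand. Upshifts of the profile mark initiation zones,
#' downshifts termination.
#'
#' @param counts A [stranded_bin_counts()].
#' @param min_total Minimal read count per bin (default 1).
#' @return A [binned_track()] of RFD values.
#' @export
compute_rfd <- function(counts, min_total = 1) {
  track_map2(counts$R, counts$F, function(r, f) {
    r0 <- ifelse(is.na(r), 0, r)
    f0 <- ifelse(is.na(f), 0, f)
    tot <- r0 + f0
    out <- (r0 - f0) / tot
    out[tot < min_total | tot == 0] <- NA_real_
    out
  })
}

#' Replicate RFD correlation in coarse windows
#'
#' Quality-control Pearson correlation between two replicates: counts are
#' summed into non-overlapping windows (default 50 kb), window RFD is
#' recomputed from the summed counts (ratio of sums, not mean of ratios),
#' and `r` is computed over windows where both replicates have more than
#' `min_reads - 1` mapped reads.
#'
#' @param a,b [stranded_bin_counts()] objects with identical geometry.
#' @param window Window width in bp (default 50000).
#' @param min_reads Qualifying windows need `R + F >= min_reads`
#'   (default 101, i.e. more than 100 reads).
#' @return Pearson correlation coefficient.
#' @export
replicate_rfd_correlation <- function(a, b, window = 50000, min_reads = 101) {
  check_geometry(a$R, b$R)
  win_rfd <- function(x) {
    R <- rebin_counts(x$R, window)
    F <- rebin_counts(x$F, window)
    r <- track_values(R); f <- track_values(F)
    r[is.na(r)] <- 0; f[is.na(f)] <- 0
    list(rfd = (r - f) / (r + f), total = r + f)
  }
  wa <- win_rfd(a); wb <- win_rfd(b)
  ok <- wa$total >= min_reads & wb$total >= min_reads
  fail_unless(sum(ok) >= 2, "fewer than 2 windows with enough reads")
  stats::cor(wa$rfd[ok], wb$rfd[ok], method = "pearson")
}
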