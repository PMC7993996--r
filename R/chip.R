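# Bin-level ChIP-seq quantification: replicate combination, sequencing
# depth normalisation to genome-mean 1 ("normalized read frequency"),
# input correction by division ("relative read frequency"), and the
# correlation/clustering QC on bin tracks.

#' Combine ChIP replicate count tracks
#'
#' Element-wise sum per bin (the read frequency); missing bins count as 0.
#'
#' @param tracks List of count [binned_track()]s with identical geometry.
#' @return A [binned_track()] of summed counts.
#' @export
combine_replicates <- function(tracks) {
  fail_unless(length(tracks) >= 1, "need at least one track")
  out <- tracks[[1]]
  if (length(tracks) == 1) return(out)
  for (t in tracks[-1]) {
    out <- track_map2(out, t, function(a, b) {
      a[is.na(a)] <- 0; b[is.na(b)] <- 0; a + b
    })
  }
  out
}

#' Normalise a count track by its genome-wide mean
#'
#' Divides every bin by the mean over non-missing bins (partial final bins
#' excluded from the mean), so the output mean over those bins is exactly
#' 1. This adjusts for sequencing depth ("normalized read frequency").
#'
#' @param counts A count [binned_track()].
#' @return The normalised [binned_track()].
#' @export
normalize_mean <- function(counts) {
  m <- track_mean(counts)
  fail_unless(is.finite(m) && m > 0,
              "track has no positive data to normalise against")
  track_map(counts, function(v) v / m)
}

#' Mask of bins without reads in the input track
#'
#' The zero-input mask is shared by every sample of an analysis run so bin
#' sets stay comparable across factors.
#'
#' @param input_counts The raw (or summed) input count track.
#' @return A named list of logical vectors, `TRUE` where input is 0 or
#'   missing.
#' @export
zero_input_mask <- function(input_counts) {
  lapply(input_counts$values, function(v) is.na(v) | v == 0)
}

#' Input-correct a mean-normalised sample track
#'
#' Bins in the zero-input mask become missing; elsewhere the output is the
#' ratio sample / input of normalised read frequencies (the "relative read
#' frequency", genome-wide scale around 1).
#'
#' @param sample_norm Mean-normalised sample track.
#' @param input_norm Mean-normalised input track.
#' @param mask Optional [zero_input_mask()]; derived from `input_norm`
#'   zeros when `NULL`.
#' @return A [binned_track()] of relative read frequencies.
#' @export
input_normalize <- function(sample_norm, input_norm, mask = NULL) {
  check_geometry(sample_norm, input_norm)
  if (is.null(mask)) mask <- zero_input_mask(input_norm)
  vals <- Map(function(s, i, m) {
    out <- s / i
    out[m] <- NA_real_
    out
  }, sample_norm$values, input_norm$values, mask)
  binned_track(vals, sample_norm$bin_width, sample_norm$chrom_sizes)
}

#' Full normalisation chain for one factor
#'
#' Convenience wrapper: sum replicates, scale to genome mean 1 and,
#' unless `input_division = FALSE`, divide by the mean-normalised input
#' under the shared zero-input mask.
#'
#' @param replicate_tracks List of count tracks for one factor.
#' @param input_counts Summed input count track (raw counts).
#' @param input_division Apply the input division step? (default TRUE).
#' @return A [binned_track()] of (relative) read frequencies.
#' @export
chip_relative_frequency <- function(replicate_tracks, input_counts,
                                    input_division = TRUE) {
  sample_norm <- normalize_mean(combine_replicates(replicate_tracks))
  if (!input_division) return(sample_norm)
  input_normalize(sample_norm, normalize_mean(input_counts),
                  mask = zero_input_mask(input_counts))
}

#' Pairwise correlation matrix and clustering of bin tracks
#'
#' Pearson correlation over bins non-missing in both tracks, followed by
#' complete-linkage hierarchical clustering on the correlation distance
#' `d = 1 - r`.
#'
#' @param tracks Named list of [binned_track()]s with identical geometry.
#' @param method Correlation method (default `"pearson"`).
#' @return A list with the correlation `matrix`, the dendrogram leaf
#'   `order` (names), and the `hclust` object.
#' @export
track_correlation_matrix <- function(tracks, method = "pearson") {
  fail_unless(length(tracks) >= 2, "need at least two tracks")
  if (is.null(names(tracks)))
    names(tracks) <- paste0("track", seq_along(tracks))
  mat <- vapply(tracks, track_values, numeric(length(track_values(
    tracks[[1]]))))
  n <- ncol(mat)
  r <- matrix(NA_real_, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok <- !is.na(mat[, i]) & !is.na(mat[, j])
      if (sum(ok) < 2) {
        warning(sprintf("fewer than 2 shared bins for %s vs %s",
                        colnames(mat)[i], colnames(mat)[j]))
        next
      }
      r[i, j] <- r[j, i] <- stats::cor(mat[ok, i], mat[ok, j],
                                       method = method)
    }
  }
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "complete")
  list(matrix = r, order = colnames(mat)[hc$order], hclust = hc)
}
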