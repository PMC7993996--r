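# BinnedTrack and StrandedBinCounts: the package's core containers for
# fixed-width binned genomic signal.
#
# Coordinates are 0-based half-open everywhere; bin i (0-based) covers
# [i*w, (i+1)*w). The final bin of a chromosome may be partial; it is kept
# (and flagged by geometry helpers) but excluded from genome-wide means.
# Missing data is NA and propagates through arithmetic -- uncovered bins
# are never silently zero.

#' Construct a binned signal track
#'
#' A `BinnedTrack` stores one numeric vector per chromosome at a fixed bin
#' width. `NA` marks missing (uncovered) bins.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param bin_width Bin width in bp.
#' @param chrom_sizes Named integer vector of chromosome sizes in bp.
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(values, bin_width, chrom_sizes) {
  fail_unless(is.list(values) && !is.null(names(values)),
              "values must be a named list")
  fail_unless(bin_width >= 1, "bin_width must be >= 1")
  chrom_sizes <- chrom_sizes[names(values)]
  fail_unless(!anyNA(chrom_sizes), "chrom_sizes missing for some chromosome")
  for (ch in names(values)) {
    nb <- n_bins(chrom_sizes[[ch]], bin_width)
    fail_unless(length(values[[ch]]) == nb,
                "chromosome %s: expected %d bins, got %d", ch, nb,
                length(values[[ch]]))
  }
  structure(list(values = lapply(values, as.numeric),
                 bin_width = as.integer(bin_width),
                 chrom_sizes = stats::setNames(as.numeric(chrom_sizes),
                                               names(values))),
            class = "BinnedTrack")
}

#' Number of bins covering a chromosome
#' @param size Chromosome size in bp.
#' @param bin_width Bin width in bp.
#' @return Integer bin count, `ceiling(size / bin_width)`.
#' @export
n_bins <- function(size, bin_width) as.integer(ceiling(size / bin_width))

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack: %d chromosome(s), bin width %d bp\n",
              length(x$values), x$bin_width))
  for (ch in names(x$values)) {
    v <- x$values[[ch]]
    cat(sprintf("  %s: %d bins, %d missing\n", ch, length(v), sum(is.na(v))))
  }
  invisible(x)
}

# Logical list flagging bins excluded from genome-wide summaries: the final
# bin when the chromosome size is not a multiple of the bin width.
partial_bin_flags <- function(track) {
  lapply(names(track$values), function(ch) {
    nbin <- length(track$values[[ch]])
    flag <- rep(FALSE, nbin)
    if (track$chrom_sizes[[ch]] %% track$bin_width != 0) flag[nbin] <- TRUE
    flag
  }) |> stats::setNames(names(track$values))
}

# Concatenated values over all chromosomes, optionally dropping flagged
# (partial) bins.
track_values <- function(track, drop_partial = FALSE) {
  if (!drop_partial) return(unlist(track$values, use.names = FALSE))
  flags <- partial_bin_flags(track)
  unlist(Map(function(v, f) v[!f], track$values, flags), use.names = FALSE)
}

# Genome-wide mean over non-missing, non-partial bins.
track_mean <- function(track) {
  mean(track_values(track, drop_partial = TRUE), na.rm = TRUE)
}

same_geometry <- function(a, b) {
  identical(a$bin_width, b$bin_width) &&
    identical(names(a$values), names(b$values)) &&
    isTRUE(all(a$chrom_sizes == b$chrom_sizes))
}

check_geometry <- function(a, b) {
  fail_unless(same_geometry(a, b),
              "tracks have incompatible bin geometry")
}

# Element-wise binary operation preserving geometry; NA propagates.
track_map2 <- function(a, b, f) {
  check_geometry(a, b)
  vals <- Map(f, a$values, b$values)
  binned_track(vals, a$bin_width, a$chrom_sizes)
}

track_map <- function(a, f) {
  binned_track(lapply(a$values, f), a$bin_width, a$chrom_sizes)
}

#' Constant-value track over a genome
#' @param value Fill value.
#' @param bin_width Bin width in bp.
#' @param chrom_sizes Named chromosome sizes.
#' @return A `BinnedTrack`.
#' @export
constant_track <- function(value, bin_width, chrom_sizes) {
  vals <- lapply(chrom_sizes, function(s) rep(value, n_bins(s, bin_width)))
  binned_track(vals, bin_width, chrom_sizes)
}

#' Re-bin a count track to a coarser bin width
#'
#' Sums counts of consecutive fine bins into coarse bins. The coarse width
#' must be a multiple of the fine width. `NA` fine bins are treated as
#' missing: a coarse bin is `NA` only if all its fine bins are `NA`.
#'
#' @param track A `BinnedTrack` of counts.
#' @param new_width Target bin width (multiple of `track$bin_width`).
#' @return A `BinnedTrack` at `new_width`.
#' @export
rebin_counts <- function(track, new_width) {
  w <- track$bin_width
  fail_unless(new_width %% w == 0, "new_width must be a multiple of bin width")
  k <- new_width %/% w
  vals <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    nb <- n_bins(track$chrom_sizes[[ch]], new_width)
    grp <- rep(seq_len(nb), each = k)[seq_along(v)]
    s <- tapply(v, grp, function(z) {
      if (all(is.na(z))) NA_real_ else sum(z, na.rm = TRUE)
    })
    as.numeric(s)
  })
  names(vals) <- names(track$values)
  binned_track(vals, new_width, track$chrom_sizes)
}

#' Construct stranded Okazaki-fragment bin counts
#'
#' Holds per-bin read counts mapped to the reverse (`R`) and forward (`F`)
#' strands, sharing `BinnedTrack` geometry.
#'
#' @param R,F Named lists of non-negative integer count vectors.
#' @param bin_width Bin width in bp.
#' @param chrom_sizes Named chromosome sizes in bp.
#' @return An object of class `StrandedBinCounts`.
#' @export
stranded_bin_counts <- function(R, F, bin_width, chrom_sizes) {
  rt <- binned_track(R, bin_width, chrom_sizes)
  ft <- binned_track(F, bin_width, chrom_sizes)
  fail_unless(all(track_values(rt) >= 0, na.rm = TRUE) &&
              all(track_values(ft) >= 0, na.rm = TRUE),
              "strand counts must be non-negative")
  structure(list(R = rt, F = ft, bin_width = rt$bin_width,
                 chrom_sizes = rt$chrom_sizes),
            class = "StrandedBinCounts")
}

#' @export
print.StrandedBinCounts <- function(x, ...) {
  cat(sprintf("StrandedBinCounts: %d chromosome(s), bin width %d bp\n",
              length(x$R$values), x$bin_width))
  invisible(x)
}
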