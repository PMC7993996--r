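# Segmentation of RFD profiles into ascending (initiation) and descending
# (termination) segments via the convexity of the Gaussian-smoothed
# profile, plus constant-RFD region calls (URR/NRR) and replication timing
# domain calls from log2(Early/Late) tracks.
#
# Convexity = convolution of the RFD profile with the second derivative of
# a Gaussian of standard deviation sigma (default 32 kb). For an ascending
# RFD shift the convexity shows a positive extremum upstream of the shift
# midpoint followed by a negative extremum downstream; the region between a
# positive and the next negative extremum of large amplitude is one AS,
# between a negative and the next positive one DS.

#' Settings for convexity-based segmentation
#'
#' @param sigma Gaussian standard deviation in bp (default 32000).
#' @param truncation Kernel truncation in multiples of `sigma`
#'   (default 4; must be at least 3).
#' @param amp_threshold Either `"auto"` (robust-SD multiple) or an absolute
#'   convexity amplitude.
#' @param amp_multiple Multiplier of the MAD-based robust SD used when
#'   `amp_threshold = "auto"` (default 2).
#' @param max_gap_bins Missing runs up to this many bins are linearly
#'   interpolated before convolution; longer gaps stay missing and split
#'   the detection domain (default 10).
#' @return A list of settings of class `ConvexitySettings`.
#' @export
convexity_settings <- function(sigma = 32000, truncation = 4,
                               amp_threshold = "auto", amp_multiple = 2,
                               max_gap_bins = 10) {
  fail_unless(sigma > 0, "sigma must be positive")
  fail_unless(truncation >= 3, "kernel truncation must be >= 3 sigma")
  structure(list(sigma = sigma, truncation = truncation,
                 amp_threshold = amp_threshold, amp_multiple = amp_multiple,
                 max_gap_bins = max_gap_bins),
            class = "ConvexitySettings")
}

# Discrete, mean-centred second-derivative-of-Gaussian kernel sampled at
# bin centres: g''(x) = (x^2 - sigma^2) / sigma^4 * dnorm(x, 0, sigma),
# truncated at +/- truncation * sigma. Mean subtraction enforces sum 0 so
# constant profiles map to exactly zero convexity.
gaussian_d2_kernel <- function(sigma_bins, truncation = 4) {
  half <- ceiling(truncation * sigma_bins)
  x <- (-half):half
  k <- (x^2 - sigma_bins^2) / sigma_bins^4 * stats::dnorm(x, 0, sigma_bins)
  k - mean(k)
}

#' Smoothed convexity of an RFD profile
#'
#' Convolves the (gap-interpolated) RFD track with the second derivative of
#' a Gaussian. Output bins within one kernel half-width of a chromosome end
#' or of an uninterpolated gap are missing.
#'
#' @param rfd A [binned_track()] of RFD values; the bin width must satisfy
#'   `bin_width <= sigma / 8`.
#' @param settings A [convexity_settings()].
#' @return A [binned_track()] of convexity values.
#' @export
smooth_convexity <- function(rfd, settings = convexity_settings()) {
  w <- rfd$bin_width
  fail_unless(w <= settings$sigma / 8,
              "bin width %d too coarse for sigma %g (need <= sigma/8)",
              w, settings$sigma)
  sigma_bins <- settings$sigma / w
  kern <- gaussian_d2_kernel(sigma_bins, settings$truncation)
  vals <- lapply(names(rfd$values), function(ch) {
    v <- rfd$values[[ch]]
    if (length(v) <= length(kern)) {
      warning(sprintf("chromosome %s shorter than the kernel; all missing",
                      ch))
      return(rep(NA_real_, length(v)))
    }
    v <- zoo::na.approx(v, maxgap = settings$max_gap_bins, na.rm = FALSE)
    as.numeric(stats::filter(v, kern, method = "convolution", sides = 2))
  })
  names(vals) <- names(rfd$values)
  binned_track(vals, w, rfd$chrom_sizes)
}

# Local extrema of a numeric vector (no NAs): returns data.frame(idx, value).
# Plateaus are compressed to their (rounded) middle index.
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3) return(data.frame(idx = integer(), value = numeric()))
  r <- rle(v)
  m <- length(r$values)
  if (m < 3) return(data.frame(idx = integer(), value = numeric()))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mids <- floor((starts + ends) / 2)
  d <- diff(r$values)
  is_max <- c(FALSE, d[-length(d)] > 0 & d[-1] < 0, FALSE)
  is_min <- c(FALSE, d[-length(d)] < 0 & d[-1] > 0, FALSE)
  keep <- is_max | is_min
  data.frame(idx = mids[keep], value = r$values[keep])
}

# Amplitude threshold: absolute, or multiple of the MAD-based robust SD of
# the genome-wide convexity track. The robust SD collapses to machine
# precision on noise-free profiles, so the auto threshold is floored at a
# small fraction of the maximum amplitude to keep floating-point ripples
# from qualifying as extrema.
resolve_threshold <- function(convexity, settings) {
  if (is.numeric(settings$amp_threshold)) return(settings$amp_threshold)
  v <- track_values(convexity)
  max(settings$amp_multiple * stats::mad(v, na.rm = TRUE),
      1e-3 * max(abs(v), na.rm = TRUE))
}

# Mean RFD over one sigma immediately outside a border (side = "left" takes
# [pos - sigma, pos), side = "right" takes [pos, pos + sigma)).
flank_mean_rfd <- function(rfd_vec, w, pos, sigma, side) {
  if (side == "left") {
    b0 <- floor((pos - sigma) / w) + 1L
    b1 <- floor((pos - 1) / w) + 1L
  } else {
    b0 <- floor(pos / w) + 1L
    b1 <- floor((pos + sigma - 1) / w) + 1L
  }
  b0 <- max(b0, 1L); b1 <- min(b1, length(rfd_vec))
  if (b1 < b0) return(NA_real_)
  mean(rfd_vec[b0:b1], na.rm = TRUE)
}

#' Detect ascending and descending RFD segments
#'
#' Identifies local extrema of the convexity track with amplitude at least
#' the threshold (sub-threshold extrema are ignored); each immediately
#' adjacent (positive, negative) extremum pair delimits one ascending
#' segment (AS) and each adjacent (negative, positive) pair one descending
#' segment (DS); same-sign neighbours delimit nothing, so a profile
#' feature contributes the extremum pair closest to its transition.
#' Each segment is annotated with
#' `delta_rfd = RFD(pos_3') - RFD(pos_5')`, where border RFD is estimated
#' as the mean RFD over one sigma immediately outside the border.
#'
#' @param convexity Output of [smooth_convexity()].
#' @param rfd The matching RFD track.
#' @param settings A [convexity_settings()].
#' @return A list with [segment_table()] components `AS` and `DS` and the
#'   resolved `threshold`.
#' @export
detect_segments <- function(convexity, rfd, settings = convexity_settings()) {
  check_geometry(convexity, rfd)
  w <- convexity$bin_width
  thr <- resolve_threshold(convexity, settings)
  as_rows <- list(); ds_rows <- list()
  for (ch in names(convexity$values)) {
    cv <- convexity$values[[ch]]
    rv <- rfd$values[[ch]]
    ok <- !is.na(cv)
    if (!any(ok)) next
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (k in which(runs$values)) {
      seg <- cv[starts[k]:ends[k]]
      ex <- local_extrema(seg)
      if (!nrow(ex)) next
      ex$idx <- ex$idx + starts[k] - 1L
      ex <- ex[abs(ex$value) >= thr, , drop = FALSE]
      if (nrow(ex) < 2) next
      sgn <- sign(ex$value)
      for (i in seq_len(nrow(ex) - 1)) {
        if (sgn[i] == sgn[i + 1]) next
        p5 <- (ex$idx[i] - 1) * w
        p3 <- ex$idx[i + 1] * w
        lm <- flank_mean_rfd(rv, w, p5, settings$sigma, "left")
        rm_ <- flank_mean_rfd(rv, w, p3, settings$sigma, "right")
        drfd <- rm_ - lm
        row <- segment_table(ch, p5, p3, drfd,
                             kind = if (sgn[i] > 0) "AS" else "DS")
        if (sgn[i] > 0) as_rows[[length(as_rows) + 1]] <- row
        else ds_rows[[length(ds_rows) + 1]] <- row
      }
    }
  }
  bind <- function(rows) if (length(rows)) do.call(rbind, rows) else
    segment_table()
  list(AS = bind(as_rows), DS = bind(ds_rows), threshold = thr)
}

#' Filter segments on length and RFD shift
#'
#' Keeps segments strictly longer than `min_length` with
#' `delta_rfd` strictly above `min_delta` (for DS lists pass the shift
#' sign via `direction = -1`, which filters on `-delta_rfd`).
#'
#' @param segments A [segment_table()].
#' @param min_length Minimal length in bp (default 20000, exclusive).
#' @param min_delta Minimal RFD shift (default 0.5, exclusive).
#' @param direction +1 for ascending (default), -1 for descending segments.
#' @return The filtered [segment_table()].
#' @export
filter_segments <- function(segments, min_length = 20000, min_delta = 0.5,
                            direction = 1) {
  if (!nrow(segments)) return(segments)
  len_ok <- (segments$end - segments$start) > min_length
  shift <- direction * segments$delta_rfd
  d_ok <- !is.na(shift) & shift > min_delta
  segments[len_ok & d_ok, , drop = FALSE]
}

#' Call constant-RFD regions (URR / NRR)
#'
#' Maximal runs of consecutive non-missing bins in which every bin
#' satisfies `|RFD| > threshold` (mode `"URR"`, unidirectionally
#' replicating regions) or `|RFD| < threshold` (mode `"NRR"`, null-RFD
#' regions), with run length at least `min_length`. Missing bins break
#' runs.
#'
#' @param rfd A [binned_track()] of RFD.
#' @param mode `"URR"` or `"NRR"`.
#' @param threshold Default 0.8 for URR, 0.15 for NRR.
#' @param min_length Default 300 kb for URR, 500 kb for NRR.
#' @return A [segment_table()] with `kind` equal to `mode` and `delta_rfd`
#'   the RFD difference between last and first bin of each run.
#' @export
detect_constant_rfd <- function(rfd, mode = c("URR", "NRR"),
                                threshold = NULL, min_length = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "URR") 0.8 else 0.15
  if (is.null(min_length)) min_length <- if (mode == "URR") 3e5 else 5e5
  w <- rfd$bin_width
  rows <- list()
  for (ch in names(rfd$values)) {
    v <- rfd$values[[ch]]
    ok <- !is.na(v) & (if (mode == "URR") abs(v) > threshold
                       else abs(v) < threshold)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      p5 <- (starts[k] - 1) * w
      p3 <- min(ends[k] * w, rfd$chrom_sizes[[ch]])
      if (p3 - p5 >= min_length) {
        rows[[length(rows) + 1]] <- segment_table(
          ch, p5, p3, v[ends[k]] - v[starts[k]], kind = mode)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else segment_table()
}

#' Smooth a replication-timing track over a centred 100-kb window
#'
#' Each 10-kb bin becomes the mean of the non-missing values in the
#' surrounding 100-kb window. As 100 kb spans an even number of 10-kb bins
#' the window is tied to the lower side: bins `i - 5` to `i + 4`.
#'
#' @param rt A [binned_track()] at 10-kb bins of log2(Early/Late).
#' @param window Window width in bp (default 100000).
#' @return The smoothed [binned_track()].
#' @export
smooth_rt <- function(rt, window = 100000) {
  w <- rt$bin_width
  fail_unless(window %% w == 0, "window must be a multiple of the bin width")
  k <- window %/% w
  lo <- -(k %/% 2); hi <- k - 1 - (k %/% 2)
  vals <- lapply(rt$values, function(v) {
    n <- length(v)
    out <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      idx <- max(1, i + lo):min(n, i + hi)
      x <- v[idx]
      if (any(!is.na(x))) out[i] <- mean(x, na.rm = TRUE)
    }
    out
  })
  binned_track(vals, w, rt$chrom_sizes)
}

#' Call replication timing domains from a smoothed timing track
#'
#' Early RTDs are maximal runs of bins with smoothed log2(Early/Late)
#' strictly above `early_thr`; late RTDs strictly below `late_thr`.
#' Missing bins break runs. Optionally, calls of the same class separated
#' by gaps up to `merge_gap` bp are merged afterwards (off by default).
#'
#' @param rt_smoothed Output of [smooth_rt()].
#' @param early_thr Early threshold (default 1.6).
#' @param late_thr Late threshold (default -2.0).
#' @param merge_gap Merge gap in bp (default 0 = no merging).
#' @return A list with [segment_table()] components `early` and `late`
#'   (`kind` `"RTD_early"` / `"RTD_late"`).
#' @export
detect_rtds <- function(rt_smoothed, early_thr = 1.6, late_thr = -2.0,
                        merge_gap = 0) {
  w <- rt_smoothed$bin_width
  call_runs <- function(pred, kind) {
    rows <- list()
    for (ch in names(rt_smoothed$values)) {
      v <- rt_smoothed$values[[ch]]
      ok <- !is.na(v) & pred(v)
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        rows[[length(rows) + 1]] <- segment_table(
          ch, (starts[k] - 1) * w,
          min(ends[k] * w, rt_smoothed$chrom_sizes[[ch]]), NA_real_,
          kind = kind)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else segment_table()
    if (merge_gap > 0 && nrow(out) > 1) out <- merge_segments(out, merge_gap)
    out
  }
  list(early = call_runs(function(v) v > early_thr, "RTD_early"),
       late = call_runs(function(v) v < late_thr, "RTD_late"))
}

# Merge same-chromosome segments separated by gaps <= merge_gap.
merge_segments <- function(segments, merge_gap) {
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  out <- segments[1, , drop = FALSE]
  for (i in seq_len(nrow(segments))[-1]) {
    last <- nrow(out)
    if (segments$chrom[i] == out$chrom[last] &&
        segments$start[i] - out$end[last] <= merge_gap) {
      out$end[last] <- max(out$end[last], segments$end[i])
    } else {
      out <- rbind(out, segments[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}
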