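# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do
#' not disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic named substream of a root seed; stays below 2^31.
seed_stream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 1) %% 2147483647)
}

# Stop unless condition holds, with sprintf-style message.
fail_unless <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# Format numbers at the package's text precision (6 significant digits).
fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

# Convert a 0-based half-open interval data.frame to IRanges (per call the
# caller is responsible for restricting to one chromosome).
iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

#' Construct a genomic interval set
#'
#' Interval sets are plain data frames with columns `chrom`, `start`, `end`
#' in 0-based half-open coordinates. Used for gap masks, peaks, marked
#' regions and constant-RFD calls.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer()) {
  fail_unless(length(chrom) == length(start) && length(start) == length(end),
              "chrom, start and end must have equal length")
  if (length(start)) {
    fail_unless(all(start >= 0), "negative interval start")
    fail_unless(all(end > start), "intervals must satisfy start < end")
  }
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

# Overlap indicator: for each query interval (one chromosome at a time),
# TRUE if it overlaps any subject interval by >= 1 bp.
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  hit <- logical(nrow(query))
  if (nrow(subject) == 0) return(hit)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    ov <- IRanges::overlapsAny(
      iranges0(query$start[qi], query$end[qi]),
      iranges0(subject$start[si], subject$end[si]))
    hit[qi] <- ov
  }
  hit
}
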