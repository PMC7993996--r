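# Readers and writers for the package's on-disk formats: bedGraph tracks,
# BED6+2 segment files, BED3 masks, gene TSV tables and the 3-column
# replication-timing TSV dialect. All coordinates on disk and in memory are
# 0-based half-open; numeric text output uses 6 significant digits.

#' Read a bedGraph file into a binned track
#'
#' Records must be non-overlapping. Records aligned to the bin grid assign
#' their value to every bin they fully cover; bins not covered by any record
#' are missing (`NA`). With `resample = TRUE`, arbitrary records are
#' converted to per-bin coverage-weighted means instead; otherwise unaligned
#' records are an error.
#'
#' @param path bedGraph file (4 columns: chrom, start, end, value).
#' @param bin_width Bin width in bp.
#' @param chrom_sizes Optional named chromosome sizes; inferred from the
#'   maximal end coordinate per chromosome when `NULL`.
#' @param resample Allow records not aligned to the bin grid.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, bin_width, chrom_sizes = NULL,
                          resample = FALSE) {
  cols <- utils::read.table(path, header = FALSE, sep = "\t",
                            comment.char = "#",
                            colClasses = c("character", "numeric", "numeric",
                                           "numeric"))
  names(cols) <- c("chrom", "start", "end", "value")
  fail_unless(all(cols$start >= 0), "negative coordinates in %s", path)
  fail_unless(all(cols$end > cols$start), "empty or inverted record in %s",
              path)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(cols$end, cols$chrom, max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes),
                                   names(chrom_sizes))
  }
  vals <- list()
  for (ch in names(chrom_sizes)) {
    nb <- n_bins(chrom_sizes[[ch]], bin_width)
    v <- rep(NA_real_, nb)
    rec <- cols[cols$chrom == ch, , drop = FALSE]
    if (nrow(rec)) {
      rec <- rec[order(rec$start), , drop = FALSE]
      fail_unless(all(rec$start[-1] >= rec$end[-nrow(rec)]) || nrow(rec) == 1,
                  "overlapping bedGraph records on %s in %s", ch, path)
      aligned <- rec$start %% bin_width == 0 &
        (rec$end %% bin_width == 0 | rec$end == chrom_sizes[[ch]])
      if (!resample) {
        fail_unless(all(aligned),
                    "record not aligned to the %d bp bin grid on %s (use resample = TRUE)",
                    bin_width, ch)
        for (i in seq_len(nrow(rec))) {
          b0 <- rec$start[i] %/% bin_width
          b1 <- ceiling(rec$end[i] / bin_width) - 1
          v[(b0:b1) + 1L] <- rec$value[i]
        }
      } else {
        cov <- rep(0, nb)
        acc <- rep(0, nb)
        for (i in seq_len(nrow(rec))) {
          b0 <- rec$start[i] %/% bin_width
          b1 <- (ceiling(rec$end[i] / bin_width)) - 1
          for (b in b0:b1) {
            lo <- max(rec$start[i], b * bin_width)
            hi <- min(rec$end[i], (b + 1) * bin_width,
                      chrom_sizes[[ch]])
            wgt <- hi - lo
            if (wgt > 0) {
              cov[b + 1L] <- cov[b + 1L] + wgt
              acc[b + 1L] <- acc[b + 1L] + wgt * rec$value[i]
            }
          }
        }
        v[cov > 0] <- acc[cov > 0] / cov[cov > 0]
      }
    }
    vals[[ch]] <- v
  }
  binned_track(vals, bin_width, chrom_sizes)
}

#' Write a binned track as bedGraph
#'
#' One record per non-missing bin, 6 significant digits.
#'
#' @param track A [binned_track()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- track$bin_width
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    keep <- which(!is.na(v))
    if (!length(keep)) next
    starts <- (keep - 1) * w
    ends <- pmin(keep * w, track$chrom_sizes[[ch]])
    writeLines(paste(ch, format(starts, scientific = FALSE, trim = TRUE),
                     format(ends, scientific = FALSE, trim = TRUE),
                     fmt_num(v[keep]), sep = "\t"), con)
  }
  invisible(path)
}

#' Construct a segment table
#'
#' Segments are RFD-profile features (ascending/descending segments,
#' constant-RFD regions, timing domains) stored as a data frame in 0-based
#' half-open coordinates with the RFD shift `delta_rfd` across the segment.
#'
#' @param chrom,start,end Coordinates.
#' @param delta_rfd RFD shift, `RFD(pos_3') - RFD(pos_5')`, in \[-2, 2\].
#' @param kind One of `"AS"`, `"DS"`, `"URR"`, `"NRR"`, `"RTD_early"`,
#'   `"RTD_late"`.
#' @param as_type Optional AS class (`"type1"`, `"type2"`, `"non_genic"`,
#'   `"genic_other"`).
#' @param orientation_flipped Logical; for type-2 segments, `TRUE` when the
#'   expressed-gene border is the left (5') border and the segment must be
#'   mirrored to put it on the right.
#' @return A `data.frame` with one row per segment.
#' @export
segment_table <- function(chrom = character(), start = integer(),
                          end = integer(), delta_rfd = numeric(),
                          kind = character(), as_type = NA_character_,
                          orientation_flipped = FALSE) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   delta_rfd = as.numeric(rep_len(delta_rfd, n)),
                   kind = as.character(rep_len(kind, n)),
                   as_type = as.character(rep_len(as_type, n)),
                   orientation_flipped = as.logical(
                     rep_len(orientation_flipped, n)),
                   stringsAsFactors = FALSE)
  if (n) fail_unless(all(df$start < df$end), "segments need start < end")
  df
}

#' Write segments as BED6+2
#'
#' Columns: chrom, start, end, name (`kind` or `kind/as_type`), score
#' (`round(1000 * |delta_rfd| / 2)` clipped to \[0, 1000\]), strand (`.`),
#' `delta_rfd` (6 significant digits) and the orientation flag (0/1).
#' Rows are sorted by chromosome (lexicographic) then start. Round-trips
#' losslessly with [read_segments_bed()] for values representable at 6
#' significant digits.
#'
#' @param segments A [segment_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand\tdelta_rfd\tflipped",
             con)
  if (nrow(segments)) {
    segments <- segments[order(segments$chrom, segments$start), ,
                         drop = FALSE]
    name <- ifelse(is.na(segments$as_type), segments$kind,
                   paste0(segments$kind, "/", segments$as_type))
    score <- round(1000 * abs(segments$delta_rfd) / 2)
    score[is.na(score)] <- 0
    score <- pmin(pmax(score, 0), 1000)
    writeLines(paste(segments$chrom,
                     format(segments$start, scientific = FALSE, trim = TRUE),
                     format(segments$end, scientific = FALSE, trim = TRUE),
                     name, score, ".", fmt_num(segments$delta_rfd),
                     as.integer(segments$orientation_flipped), sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read a BED6+2 segment file written by [write_segments_bed()]
#' @param path Input file.
#' @return A [segment_table()].
#' @export
read_segments_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(segment_table())
  f <- strsplit(lines, "\t", fixed = TRUE)
  m <- do.call(rbind, f)
  name <- m[, 4]
  has_type <- grepl("/", name, fixed = TRUE)
  kind <- ifelse(has_type, sub("/.*$", "", name), name)
  as_type <- ifelse(has_type, sub("^[^/]*/", "", name), NA_character_)
  segment_table(chrom = m[, 1], start = as.numeric(m[, 2]),
                end = as.numeric(m[, 3]),
                delta_rfd = suppressWarnings(as.numeric(m[, 7])),
                kind = kind, as_type = as_type,
                orientation_flipped = m[, 8] == "1")
}

#' Write an interval set as BED3
#' @param intervals An [interval_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed3 <- function(intervals, path) {
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3 file as an interval set
#' @param path Input file.
#' @return An [interval_set()].
#' @export
read_bed3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(interval_set())
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  interval_set(m[, 1], as.numeric(m[, 2]), as.numeric(m[, 3]))
}

#' Write a gene table as TSV
#' @param genes Gene table (see [build_genome()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  for (col in c("exonic_length_kb", "tpm")) {
    if (col %in% names(out)) out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene table TSV
#' @param path Input file.
#' @return A gene `data.frame`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df
}

#' Read a replication-timing TSV (chrom, position, log2 ratio)
#'
#' Accepts the common 3-column dialect of pre-computed log2(Early/Late)
#' tables in which `position` is the 0-based start of a fixed-width bin.
#'
#' @param path Input file.
#' @param bin_width Bin width in bp (default 10 kb).
#' @param chrom_sizes Optional named sizes; inferred when `NULL`.
#' @param header Does the file carry a header line?
#' @return A [binned_track()].
#' @export
read_rt_table <- function(path, bin_width = 10000, chrom_sizes = NULL,
                          header = FALSE) {
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "position", "ratio")
  fail_unless(all(df$position %% bin_width == 0),
              "positions not aligned to the %d bp grid", bin_width)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(df$position + bin_width, df$chrom, max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes),
                                   names(chrom_sizes))
  }
  vals <- list()
  for (ch in names(chrom_sizes)) {
    v <- rep(NA_real_, n_bins(chrom_sizes[[ch]], bin_width))
    rec <- df[df$chrom == ch, , drop = FALSE]
    v[rec$position %/% bin_width + 1L] <- as.numeric(rec$ratio)
    vals[[ch]] <- v
  }
  binned_track(vals, bin_width, chrom_sizes)
}

#' Locate assembly gaps (runs of Ns) in a FASTA file
#'
#' Returns maximal runs of at least `min_run` consecutive `N`/`n` per
#' sequence, in 0-based half-open coordinates. With the default
#' `min_run = 21` this masks regions of more than 20 consecutive Ns.
#'
#' @param fasta_path FASTA file.
#' @param min_run Minimal run length to report.
#' @return An [interval_set()].
#' @export
n_gap_mask <- function(fasta_path, min_run = 21) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- list()
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    if (!nchar(s)) next
    hits <- gregexpr(sprintf("[Nn]{%d,}", min_run), s)[[1]]
    if (hits[1] == -1) next
    len <- attr(hits, "match.length")
    out[[length(out) + 1]] <- interval_set(
      rep(names(seqs)[i], length(hits)),
      as.integer(hits) - 1L, as.integer(hits) - 1L + len)
  }
  if (!length(out)) return(interval_set())
  do.call(rbind, out)
}

#' Write a synthetic genome FASTA with planted N gaps
#'
#' Random A/C/G/T sequence per chromosome with `N` runs at the supplied
#' gap intervals. Intended for desk-scale fixtures exercising
#' [n_gap_mask()] and mask-aware shuffling.
#'
#' @param chrom_sizes Named sizes in bp.
#' @param path Output FASTA.
#' @param gaps Optional [interval_set()] of N runs.
#' @param seed Integer seed for the random sequence.
#' @return `path`, invisibly.
#' @export
write_synthetic_fasta <- function(chrom_sizes, path, gaps = NULL, seed = 1) {
  seqs <- with_seed(seed, {
    vapply(names(chrom_sizes), function(ch) {
      s <- sample(c("A", "C", "G", "T"), chrom_sizes[[ch]], replace = TRUE)
      if (!is.null(gaps)) {
        g <- gaps[gaps$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(g))) s[(g$start[i] + 1):g$end[i]] <- "N"
      }
      paste(s, collapse = "")
    }, character(1))
  })
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(chrom_sizes)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
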