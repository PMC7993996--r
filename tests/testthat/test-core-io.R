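# Readers/writers: bedGraph bin semantics, BED6+2 segment round trips,
# N-gap masking.

test_that("read_bedgraph assigns aligned records and leaves gaps missing", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chrT\t0\t1000\t5.0",
               "chrT\t2000\t4000\t-1.5"), path)
  tr <- read_bedgraph(path, 1000,
                      chrom_sizes = c(chrT = 6000))
  expect_equal(tr$values$chrT, c(5, NA, -1.5, -1.5, NA, NA))
})

test_that("read_bedgraph rejects bad records", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chrT\t500\t1500\t4.0", path)
  expect_error(read_bedgraph(path, 1000, c(chrT = 3000)), "not aligned")
  writeLines(c("chrT\t0\t2000\t1", "chrT\t1000\t3000\t2"), path)
  expect_error(read_bedgraph(path, 1000, c(chrT = 3000)), "overlapping")
  writeLines("chrT\t-5\t1000\t1", path)
  expect_error(read_bedgraph(path, 1000, c(chrT = 3000)), "negative")
})

test_that("resampling computes coverage-weighted means", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  # bin 0: 500 bp of 4.0 -> mean 4; bin 1: 500 bp of 4 + 500 of 8 -> 6
  writeLines(c("chrT\t500\t1500\t4.0", "chrT\t1500\t2000\t8.0"), path)
  tr <- read_bedgraph(path, 1000, c(chrT = 3000), resample = TRUE)
  expect_equal(tr$values$chrT, c(4, 6, NA))
})

test_that("bedGraph tracks round-trip at 6 significant digits", {
  set.seed(42)
  v <- signif(stats::rnorm(40), 6)
  v[c(3, 17)] <- NA
  tr <- vec_track(v)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path, 1000, tr$chrom_sizes)
  expect_identical(back$values$chrT, tr$values$chrT)
})

test_that("segment BED6+2 writes scores and round-trips", {
  seg <- segment_table("chr1", 100000, 160000, 1.0, "AS")
  path <- withr::local_tempfile(fileext = ".bed")
  write_segments_bed(seg, path)
  line <- strsplit(readLines(path)[2], "\t")[[1]]
  expect_equal(as.numeric(line[5]), 500)  # 1000 * |1.0| / 2
  # empty set -> header only -> reads back empty
  write_segments_bed(segment_table(), path)
  expect_equal(nrow(read_segments_bed(path)), 0)
})

test_that("100 random segments survive a write-read cycle", {
  set.seed(7)
  n <- 100
  starts <- sort(sample.int(1e6, n)) * 10
  seg <- segment_table(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = starts, end = starts + sample.int(1e5, n),
    delta_rfd = signif(stats::runif(n, -2, 2), 6),
    kind = sample(c("AS", "DS", "URR", "NRR"), n, replace = TRUE),
    as_type = sample(c(NA, "type1", "type2", "non_genic"), n,
                     replace = TRUE),
    orientation_flipped = sample(c(TRUE, FALSE), n, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".bed")
  write_segments_bed(seg, path)
  back <- read_segments_bed(path)
  ord <- order(seg$chrom, seg$start)
  expect_equal(back$chrom, seg$chrom[ord])
  expect_equal(back$start, seg$start[ord])
  expect_equal(back$end, seg$end[ord])
  expect_equal(back$delta_rfd, seg$delta_rfd[ord])
  expect_equal(back$kind, seg$kind[ord])
  expect_equal(back$as_type, seg$as_type[ord])
  expect_equal(back$orientation_flipped, seg$orientation_flipped[ord])
})

test_that("n_gap_mask reports maximal runs of more than 20 Ns", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", paste0("ACGT", strrep("N", 25), "ACGT"),
               ">s2", paste0("AC", strrep("N", 20), "GT")), path)
  mask <- n_gap_mask(path)
  expect_equal(nrow(mask), 1)
  expect_equal(mask$start, 4)
  expect_equal(mask$end, 29)
})

test_that("n_gap_mask matches a brute-force scan on random sequence", {
  set.seed(3)
  bases <- sample(c("A", "C", "G", "T"), 5000, replace = TRUE)
  for (s in c(100, 900, 3000)) bases[s:(s + 20 + s %/% 500)] <- "N"
  seq <- paste(bases, collapse = "")
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r", seq), path)
  mask <- n_gap_mask(path, min_run = 21)
  # oracle: linear scan for runs of >= 21 Ns
  is_n <- bases == "N"
  r <- rle(is_n)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= 21
  expect_equal(mask$start, starts[keep] - 1)
  expect_equal(mask$end, ends[keep])
})

test_that("rt tables in the 3-column dialect load onto the bin grid", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t0\t1.25", "chr1\t20000\t-2.5"), path)
  tr <- read_rt_table(path, 10000, c(chr1 = 40000))
  expect_equal(tr$values$chr1, c(1.25, NA, -2.5, NA))
})

test_that("synthetic FASTA with planted gaps feeds the mask finder", {
  path <- withr::local_tempfile(fileext = ".fa")
  gaps <- interval_set(c("c1", "c1"), c(100, 500), c(160, 540))
  write_synthetic_fasta(c(c1 = 1000), path, gaps = gaps, seed = 2)
  mask <- n_gap_mask(path)
  expect_equal(mask$start, c(100, 500))
  expect_equal(mask$end, c(160, 540))
})
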