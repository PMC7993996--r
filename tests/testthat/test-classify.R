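# AS typing, mark subsetting, peak intersection and region means.

test_that("AS types follow the flanking-transcription rules", {
  as_seg <- segment_table(rep("c1", 3), c(1e5, 4e5, 7e5),
                          c(1.6e5, 4.6e5, 7.6e5), 1.0, "AS")
  genes <- data.frame(
    chrom = "c1",
    start = c(80000, 165000, 380000, 725000),
    end = c(90000, 200000, 395000, 745000),
    tpm = c(10, 8, 9, 2))
  out <- classify_as(as_seg, genes)
  # AS1: expressed gene ending 10 kb left, expressed gene 5 kb right
  expect_equal(out$as_type[1], "type1")
  # AS2: expressed gene only left of the 5' border -> flipped type 2
  expect_equal(out$as_type[2], "type2")
  expect_true(out$orientation_flipped[2])
  # AS3: only a silent gene within reach -> genic but untyped
  expect_equal(out$as_type[3], "genic_other")
  # nearest gene 25 kb away on an otherwise empty chromosome
  far <- classify_as(segment_table("c1", 1e5, 1.5e5, 1, "AS"),
                     data.frame(chrom = "c1", start = 175000, end = 2e5,
                                tpm = 50))
  expect_equal(far$as_type, "non_genic")
  # the classes partition the list
  expect_true(all(out$as_type %in%
                    c("type1", "type2", "non_genic", "genic_other")))
})

test_that("type-2 orientation puts the expressed border on the right", {
  as_seg <- segment_table("c1", 4e5, 4.6e5, 1.0, "AS")
  right_gene <- data.frame(chrom = "c1", start = 465000, end = 485000,
                           tpm = 20)
  out <- classify_as(as_seg, right_gene)
  expect_equal(out$as_type, "type2")
  expect_false(out$orientation_flipped)
})

test_that("mark subsetting partitions by genome mean and SD", {
  set.seed(13)
  v <- c(rep(c(0.8, 1.2), 500))  # mean 1, sd ~0.2
  tr <- vec_track(v, bin_width = 10000)
  iv <- segment_table(rep("chrT", 3), c(0, 2e5, 4e5),
                      c(1e5, 3e5, 5e5), NA_real_, "AS")
  # plant interval means 1.4 / 0.9 / 1.1
  tr$values$chrT[1:10] <- 1.4
  tr$values$chrT[21:30] <- 0.9
  tr$values$chrT[41:50] <- 1.1
  res <- subset_by_mark(iv, tr)
  expect_equal(res$high$start, 0)
  expect_equal(res$low$start, 2e5)
  expect_equal(res$neither$start, 4e5)
  expect_equal(nrow(res$high) + nrow(res$low) + nrow(res$neither),
               nrow(iv))
  # raising the multiple can only shrink the high set
  res2 <- subset_by_mark(iv, tr, sd_multiple = 10)
  expect_lte(nrow(res2$high), nrow(res$high))
})

test_that("replicate peak intersection keeps first-set peaks hit by all", {
  a <- interval_set(rep("c1", 3), c(100, 500, 900), c(200, 600, 1000))
  expect_equal(intersect_replicate_peaks(list(a, a, a)), a)
  disjoint <- interval_set("c1", 2000, 2100)
  expect_equal(nrow(intersect_replicate_peaks(list(a, disjoint))), 0)
  expect_equal(nrow(intersect_replicate_peaks(
    list(a, interval_set()))), 0)
})

test_that("peak intersection matches a brute-force overlap oracle", {
  set.seed(14)
  rand_set <- function(n) {
    s <- sort(sample.int(5000, n))
    interval_set(rep("c1", n), s * 10, s * 10 + sample.int(300, n))
  }
  sets <- lapply(c(30, 25, 20), rand_set)
  got <- intersect_replicate_peaks(sets)
  # oracle: merge set 1, then test every merged peak against both others
  m <- IRanges::reduce(IRanges::IRanges(sets[[1]]$start + 1,
                                        sets[[1]]$end))
  keep <- vapply(seq_along(m), function(i) {
    all(vapply(sets[-1], function(s) {
      any(s$start + 1 <= IRanges::end(m)[i] &
            s$end >= IRanges::start(m)[i])
    }, logical(1)))
  }, logical(1))
  expect_equal(got$start, IRanges::start(m)[keep] - 1)
  expect_equal(got$end, IRanges::end(m)[keep])
})

test_that("region means report per-class means, SEM and ratios", {
  v <- c(rep(1.4, 50), rep(1.0, 50))
  tr <- vec_track(v, bin_width = 10000)
  classes <- list(
    early = interval_set("chrT", 0, 5e5),
    late = interval_set("chrT", 5e5, 1e6))
  res <- region_mean_frequency(classes, tr)
  expect_equal(res$mean, c(1.4, 1.0))
  expect_equal(res$ratio_to_first, c(1.0, 1.4))
  same <- region_mean_frequency(list(a = classes$early,
                                     b = classes$early), tr)
  expect_equal(same$ratio_to_first[2], 1.0)
  # gene exclusion removes bins
  genes <- data.frame(chrom = "chrT", start = 0, end = 3e5)
  res2 <- region_mean_frequency(classes, tr, genes = genes)
  expect_equal(res2$n_bins[1], 19)  # genes +/- 10 kb drop 31 of 50 bins
  expect_error(region_mean_frequency(
    list(x = interval_set("chrT", 0, 5e5)), tr,
    genes = data.frame(chrom = "chrT", start = 0, end = 1e6)),
    "no qualifying bins")
})
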