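# Locus-aligned aggregate profiles and the decile histogram.

test_that("constant tracks give flat border profiles with zero SEM", {
  seg <- segment_table(rep("chrT", 4), c(1e5, 3e5, 5e5, 7e5),
                       c(1.6e5, 3.6e5, 5.6e5, 7.6e5), 1, "AS")
  s <- vec_track(rep(2, 1000))
  i <- vec_track(rep(2, 1000))
  prof <- border_profile(seg, s, i)
  expect_true(all(prof$profile == 1))
  expect_true(all(prof$sem_sample == 0))
  expect_equal(nrow(prof), 60)  # -50 kb .. +10 kb at 1 kb
})

test_that("a single locus reproduces its own ratio track", {
  set.seed(15)
  sv <- runif(1000, 0.5, 2); iv <- runif(1000, 0.5, 2)
  seg <- segment_table("chrT", 5e5, 5.6e5, 1, "AS")
  prof <- border_profile(seg, vec_track(sv), vec_track(iv))
  idx <- (5e5 / 1000) + seq(-50, 9)  # bins at the aligned offsets
  expect_equal(prof$profile, sv[idx + 1] / iv[idx + 1],
               tolerance = 1e-12)
})

test_that("3' alignment mirrors and flipped segments swap borders", {
  v <- rep(1, 1000); v[481:520] <- 2  # plateau right of position 480 kb
  s <- vec_track(v)
  seg5 <- segment_table("chrT", 4.8e5, 5.5e5, 1, "AS")
  p5 <- border_profile(seg5, s, NULL, align = "5p")
  # inside offsets (>= 0) sit in the plateau
  expect_true(all(p5$profile[p5$offset >= 0] == 2))
  expect_true(all(p5$profile[p5$offset < -2000] == 1))
  seg3 <- segment_table("chrT", 4.5e5, 5.2e5, 1, "AS")
  p3 <- border_profile(seg3, s, NULL, align = "3p")
  expect_true(all(p3$profile[p3$offset >= 0] == 2))
  flipped <- segment_table("chrT", 4.5e5, 5.2e5, 1, "AS",
                           orientation_flipped = TRUE)
  pf <- border_profile(flipped, s, NULL, align = "5p")
  expect_equal(pf$profile, p3$profile)
})

test_that("short segments are skipped and counted", {
  seg <- segment_table(rep("chrT", 2), c(1e5, 3e5), c(1.15e5, 3.6e5),
                       1, "AS")
  prof <- border_profile(seg, vec_track(rep(1, 1000)), NULL)
  expect_equal(attr(prof, "n_skipped"), 1)
})

test_that("metagene profiles orient minus-strand genes 5' to 3'", {
  v <- rep(1, 1000)
  v[301:1000] <- 2  # high downstream of position 300 kb
  genes <- data.frame(chrom = "chrT", start = 3e5, end = 3.5e5,
                      strand = "+", tpm = 50)
  pplus <- suppressWarnings(
    gene_metaprofile(genes, vec_track(v), NULL, align = "TSS"))
  expect_true(all(pplus$high$profile[pplus$high$offset >= 1000] == 2))
  expect_true(all(pplus$high$profile[pplus$high$offset < 0] == 1))
  gminus <- data.frame(chrom = "chrT", start = 2.5e5, end = 3e5,
                       strand = "-", tpm = 50)
  # for the minus gene the TSS is at 300 kb and upstream lies above it
  pminus <- suppressWarnings(
    gene_metaprofile(gminus, vec_track(v), NULL, align = "TSS"))
  expect_true(all(pminus$high$profile[pminus$high$offset < -1000] == 2))
  expect_true(all(pminus$high$profile[pminus$high$offset >= 0] == 1))
})

test_that("metagene eligibility needs length > 30 kb and 15 kb isolation", {
  tr <- vec_track(rep(1, 2000))
  genes <- data.frame(
    chrom = "chrT",
    start = c(1e5, 2e5, 2.42e5, 9e5),
    end = c(1.29e5, 2.4e5, 2.9e5, 9.5e5),
    strand = "+", tpm = c(50, 50, 50, 50))
  suppressWarnings(prof <- gene_metaprofile(genes, tr, NULL))
  # gene 1 is 29 kb (too short); genes 2 and 3 are 2 kb apart; only
  # gene 4 qualifies
  expect_equal(max(prof$high$n), 1)
})

test_that("decile histogram columns are probability distributions", {
  set.seed(16)
  rt <- vec_track(stats::rnorm(5000), bin_width = 10000)
  chip_const <- vec_track(rep(1.7, 5000), bin_width = 10000)
  h <- rt_decile_hist2d(chip_const, rt)
  expect_equal(colSums(h$matrix), rep(1, 10), tolerance = 1e-9)
  expect_true(all(apply(h$matrix, 2, max) == 1))  # point mass per column
  # chip equal to the timing rank: strictly increasing column means
  rnk <- vec_track(rank(rt$values$chrT) / 5000, bin_width = 10000)
  h2 <- rt_decile_hist2d(rnk, rt)
  expect_true(all(diff(h2$stats$mean) > 0))
})

test_that("restriction limits histogram windows to given intervals", {
  rt <- vec_track(seq(-3, 3, length.out = 1000), bin_width = 10000)
  chip <- vec_track(rep(1, 1000), bin_width = 10000)
  h <- rt_decile_hist2d(chip, rt,
                        restriction = interval_set("chrT", 0, 2e6))
  expect_equal(h$n, 200)
})

test_that("SEM bands shrink like 1 / sqrt(n) across locus subsamples", {
  set.seed(17)
  v <- stats::rnorm(40000, mean = 1, sd = 0.4)
  tr <- vec_track(v, bin_width = 1000)
  starts <- seq(1e5, 3.8e7, by = 2.3e5)[1:160]
  seg <- segment_table(rep("chrT", 160), starts, starts + 3e4, 1, "AS")
  p_small <- border_profile(seg[1:40, ], tr, NULL)
  p_large <- border_profile(seg, tr, NULL)
  ratio <- mean(p_small$sem_sample / p_large$sem_sample)
  expect_equal(ratio, 2, tolerance = 0.25)
})
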