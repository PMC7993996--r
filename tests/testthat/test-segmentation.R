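# Convexity segmentation, constant-RFD calls, RT smoothing and domains.

logistic_step <- function(n, x0, h, scale, w = 1000, base = -h / 2) {
  x <- (seq_len(n) - 0.5) * w
  base + h / (1 + exp(-(x - x0) / scale))
}

test_that("convexity of constant and long-linear profiles is zero", {
  cs <- convexity_settings()
  flat <- vec_track(rep(0.4, 2000))
  cv <- smooth_convexity(flat, cs)
  expect_true(all(abs(cv$values$chrT) < 1e-12, na.rm = TRUE))
  ramp <- vec_track(seq(-1, 1, length.out = 4000))
  cvr <- smooth_convexity(ramp, cs)
  interior <- cvr$values$chrT[500:3500]
  expect_true(all(abs(interior) < 1e-9, na.rm = TRUE))
})

test_that("convexity extrema of a logistic shift match a finite-difference
           oracle", {
  n <- 3000; x0 <- 1.5e6
  prof <- logistic_step(n, x0, h = 1, scale = 7000)
  cs <- convexity_settings()
  cv <- smooth_convexity(vec_track(prof), cs)$values$chrT
  imax <- which.max(cv); imin <- which.min(cv)
  # oracle: Gaussian-smooth the profile directly, then second difference
  sb <- cs$sigma / 1000
  half <- ceiling(4 * sb)
  g <- dnorm((-half):half, 0, sb); g <- g / sum(g)
  sm <- as.numeric(stats::filter(prof, g, sides = 2))
  d2 <- c(NA, diff(sm, differences = 2), NA)
  expect_lte(abs(imax - which.max(d2)), 1)
  expect_lte(abs(imin - which.min(d2)), 1)
  # extrema straddle the shift midpoint, positive upstream
  expect_lt(imax * 1000, x0)
  expect_gt(imin * 1000, x0)
  expect_equal(cv[imax], -cv[imin], tolerance = 1e-6)
})

test_that("an isolated ascending shift yields one AS and no DS", {
  prof <- logistic_step(3000, 1.5e6, h = 1, scale = 7000)
  tr <- vec_track(prof)
  cs <- convexity_settings()
  cv <- smooth_convexity(tr, cs)
  seg <- detect_segments(cv, tr, cs)
  expect_equal(nrow(seg$AS), 1)
  expect_equal(nrow(seg$DS), 0)
  expect_lt(seg$AS$start, 1.5e6)
  expect_gt(seg$AS$end, 1.5e6)
  expect_equal(seg$AS$delta_rfd, 1.0, tolerance = 0.05)
  # flat profile: nothing
  segf <- detect_segments(smooth_convexity(vec_track(rep(0, 3000)), cs),
                          vec_track(rep(0, 3000)), cs)
  expect_equal(nrow(segf$AS) + nrow(segf$DS), 0)
})

test_that("negating the profile swaps AS and DS with coordinates intact", {
  set.seed(5)
  gb <- build_genome(small_config(seed = 31))
  rfd <- true_rfd(gb$truth)
  neg <- repliseg:::track_map(rfd, function(v) -v)
  cs <- convexity_settings()
  a <- detect_segments(smooth_convexity(rfd, cs), rfd, cs)
  b <- detect_segments(smooth_convexity(neg, cs), neg, cs)
  expect_equal(b$DS[, c("chrom", "start", "end")],
               a$AS[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
  expect_equal(b$DS$delta_rfd, -a$AS$delta_rfd, tolerance = 1e-9)
  expect_equal(b$AS[, c("chrom", "start", "end")],
               a$DS[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
})

test_that("AS never overlap each other and alternate with DS", {
  gb <- build_genome(small_config(seed = 41))
  rfd <- compute_rfd(simulate_okseq(gb$truth, seed = 99))
  cs <- convexity_settings()
  seg <- detect_segments(smooth_convexity(rfd, cs), rfd, cs)
  both <- rbind(cbind(seg$AS, k = "AS"), cbind(seg$DS, k = "DS"))
  both <- both[order(both$chrom, both$start), ]
  for (ch in unique(both$chrom)) {
    s <- both[both$chrom == ch, ]
    if (nrow(s) < 2) next
    expect_true(all(s$start[-1] >= s$end[-nrow(s)] - 1000))
    expect_true(all(s$k[-1] != s$k[-nrow(s)]))
  }
})

test_that("raising the amplitude threshold never adds segments", {
  gb <- build_genome(small_config(seed = 51))
  rfd <- compute_rfd(simulate_okseq(gb$truth, seed = 7))
  cv <- smooth_convexity(rfd, convexity_settings())
  base_thr <- repliseg:::resolve_threshold(cv, convexity_settings())
  counts <- vapply(c(0.5, 1, 2, 4), function(mult) {
    cs <- convexity_settings(amp_threshold = base_thr * mult)
    seg <- detect_segments(cv, rfd, cs)
    nrow(seg$AS) + nrow(seg$DS)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segment filters use strict inequalities", {
  seg <- segment_table(rep("c", 3), c(0, 1e5, 2e5),
                       c(19999, 120001, 220000),
                       delta_rfd = c(0.6, 0.6, 0.5), kind = "AS")
  kept <- filter_segments(seg)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, 1e5)  # 20001 bp long, shift 0.6
})

test_that("constant-RFD calls honour thresholds and run lengths", {
  v <- c(rep(0.05, 100), rep(0.9, 350), rep(0.05, 550), rep(0.9, 250),
         rep(0.5, 100))
  tr <- vec_track(v)
  urr <- detect_constant_rfd(tr, "URR")
  expect_equal(nrow(urr), 1)
  expect_equal(c(urr$start, urr$end), c(100000, 450000))
  # the 250-kb high strip is below the 300 kb minimum
  nrr <- detect_constant_rfd(tr, "NRR")
  expect_equal(nrow(nrr), 1)
  expect_equal(c(nrr$start, nrr$end), c(450000, 1000000))
  # a single out-of-band bin breaks an NRR run
  v2 <- rep(0.05, 600); v2[300] <- 0.2
  expect_equal(nrow(detect_constant_rfd(vec_track(v2), "NRR")), 0)
})

test_that("RT smoothing is a 100-kb moving mean tied to the lower side", {
  const <- vec_track(rep(1.3, 60), bin_width = 10000)
  expect_equal(smooth_rt(const)$values$chrT, rep(1.3, 60))
  spike <- rep(0, 60); spike[30] <- 10
  sm <- smooth_rt(vec_track(spike, bin_width = 10000))$values$chrT
  expect_equal(which(sm == 1), 26:35)  # bins i-5..i+4 cover the spike
  set.seed(6)
  v <- stats::rnorm(200)
  v[sample(200, 20)] <- NA
  sm2 <- smooth_rt(vec_track(v, bin_width = 10000))$values$chrT
  oracle <- vapply(seq_along(v), function(i) {
    win <- v[max(1, i - 5):min(200, i + 4)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
  expect_equal(sm2, oracle, tolerance = 1e-12)
})

test_that("RTD calls are strict and span constant chromosomes", {
  tr <- vec_track(rep(2, 80), bin_width = 10000)
  rtds <- detect_rtds(smooth_rt(tr))
  expect_equal(nrow(rtds$early), 1)
  expect_equal(c(rtds$early$start, rtds$early$end), c(0, 800000))
  at_thr <- vec_track(rep(1.6, 80), bin_width = 10000)
  expect_equal(nrow(detect_rtds(smooth_rt(at_thr))$early), 0)
  # merge_gap closes small gaps when requested
  v <- c(rep(2.5, 20), rep(2.5, 0), rep(-3, 1), rep(2.5, 20), rep(-3, 40))
  tr2 <- vec_track(v, bin_width = 10000)
  plain <- detect_rtds(tr2)
  merged <- detect_rtds(tr2, merge_gap = 20000)
  expect_gt(nrow(plain$early), nrow(merged$early))
})
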