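# The generator: determinism, planted-architecture contracts, sampling
# models.

test_that("identical configs give identical genomes; seeds differ", {
  cfg <- small_config(seed = 71)
  g1 <- build_genome(cfg)
  g2 <- build_genome(small_config(seed = 71))
  expect_identical(g1$truth$segments, g2$truth$segments)
  expect_identical(g1$genes, g2$genes)
  g3 <- build_genome(small_config(seed = 72))
  expect_false(identical(g1$genes$start, g3$genes$start))
  # OK-seq and ChIP draws are reproducible too
  o1 <- simulate_okseq(g1$truth)
  o2 <- simulate_okseq(g2$truth)
  expect_identical(o1$R$values, o2$R$values)
  c1 <- simulate_chip(g1$truth, "Orc2")
  c2 <- simulate_chip(g2$truth, "Orc2")
  expect_identical(c1$values, c2$values)
})

test_that("type fractions are realised by construction", {
  cfg <- small_config(seed = 73, frac_type1 = 1, frac_type2 = 0)
  gb <- build_genome(cfg)
  iz <- gb$truth$segments[gb$truth$segments$kind == "IZ", ]
  as_seg <- segment_table(iz$chrom, iz$start, iz$end, 1, "AS")
  typed <- classify_as(as_seg, gb$genes)
  expect_true(all(typed$as_type == "type1"))
  # no genes at all: every IZ is non-genic
  cfg0 <- small_config(seed = 74, frac_type1 = 0, frac_type2 = 0,
                       n_background_genes = 0)
  gb0 <- build_genome(cfg0)
  expect_equal(nrow(gb0$genes), 0)
  iz0 <- gb0$truth$segments[gb0$truth$segments$kind == "IZ", ]
  typed0 <- classify_as(segment_table(iz0$chrom, iz0$start, iz0$end, 1,
                                      "AS"), gb0$genes)
  expect_true(all(typed0$as_type == "non_genic"))
  # mixed default fractions are matched exactly
  gbm <- build_genome(small_config(seed = 75))
  izm <- gbm$truth$segments[gbm$truth$segments$kind == "IZ", ]
  expect_equal(sum(izm$as_type == "type1"), round(0.4 * 8))
  expect_equal(sum(izm$as_type == "type2"), round(0.35 * 8))
})

test_that("gene TPMs sum to 1e6 and flanking genes are expressed", {
  gb <- build_genome(small_config(seed = 76))
  expect_equal(sum(gb$genes$tpm), 1e6, tolerance = 0.01)
  expect_true(all(gb$genes$tpm[gb$genes$role == "flank"] > 3))
  recomputed <- compute_tpm(gb$genes$read_count,
                            gb$genes$exonic_length_kb)
  expect_gt(stats::cor(recomputed, gb$genes$tpm), 0.99)
})

test_that("the noise-free RFD honours the planted plateaus", {
  gb <- build_genome(small_config(seed = 77))
  truth <- gb$truth
  rfd <- true_rfd(truth)
  v <- rfd$values$chr1
  expect_true(all(v >= -1 & v <= 1))
  w <- truth$config$bin_width
  seg <- truth$segments
  for (i in which(seg$kind == "URR")) {
    bins <- (seg$start[i] / w + 1):(seg$end[i] / w)
    expect_true(all(abs(v[bins]) > 0.8))
  }
  for (i in which(seg$kind == "NRR")) {
    bins <- (seg$start[i] / w + 1):(seg$end[i] / w)
    expect_true(all(abs(v[bins]) < 0.15))
  }
})

test_that("an isolated full-efficiency IZ spans the full RFD range", {
  truth <- manual_truth(plant_iz("chr1", 4.98e6, 5.02e6, 1))
  rfd <- true_rfd(truth)
  v <- rfd$values$chr1
  # just outside the zone the profile sits at -1 / +1
  expect_equal(v[4940], -1, tolerance = 0.01)
  expect_equal(v[5060], 1, tolerance = 0.01)
  drfd <- v[5060] - v[4940]
  expect_equal(drfd, 2, tolerance = 0.02)
})

test_that("a featureless chromosome has identically zero RFD", {
  truth <- manual_truth(plant_iz("chr1", 1, 2, 1)[0, ])
  v <- true_rfd(truth)$values$chr1
  expect_true(all(v == 0))
})

test_that("two equal IZs separated by a termination zone cross zero at
           its midpoint", {
  segs <- rbind(plant_iz("chr1", 4.0e6, 4.05e6, 0.8),
                plant_iz("chr1", 4.45e6, 4.5e6, 0.8))
  truth <- manual_truth(segs)
  v <- true_rfd(truth)$values$chr1
  mid_bin <- 4.25e6 / 1000  # the midpoint falls on this bin boundary
  expect_equal(mean(v[mid_bin + 0:1]), 0, tolerance = 0.005)
  # odd symmetry around the midpoint
  expect_equal(v[mid_bin - 50], -v[mid_bin + 51], tolerance = 0.005)
})

test_that("OK-seq sampling follows the Poisson-binomial model", {
  truth <- manual_truth(plant_iz("chr1", 1, 2, 1)[0, ])  # RFD = 0
  ok <- simulate_okseq(truth, depth = 100, seed = 5)
  R <- ok$R$values$chr1; F <- ok$F$values$chr1
  n <- length(R)
  expect_equal(mean(R + F), 100, tolerance = 0.5)
  # empirical RFD close to the truth (0): per-bin binomial sd is about
  # 0.1 at depth 100, so the mean over ~1e4 bins has sd about 0.001
  rfd_hat <- mean((R - F) / (R + F), na.rm = TRUE)
  expect_lt(abs(rfd_hat), 0.005)
  # zero depth silences everything
  ok0 <- simulate_okseq(truth, depth = 0, seed = 5)
  expect_true(all(ok0$R$values$chr1 + ok0$F$values$chr1 == 0))
  expect_true(all(is.na(compute_rfd(ok0)$values$chr1)))
})

test_that("strand counts track the local fork direction", {
  gb <- build_genome(small_config(seed = 78))
  truth <- gb$truth
  ok <- simulate_okseq(truth, depth = 150, seed = 6)
  rfd_true <- true_rfd(truth)$values$chr1
  urr_bins <- which(rfd_true > 0.85)
  frac_R <- sum(ok$R$values$chr1[urr_bins]) /
    sum(ok$R$values$chr1[urr_bins] + ok$F$values$chr1[urr_bins])
  expect_equal(frac_R, (1 + 0.9) / 2, tolerance = 0.01)
})

test_that("H4K20me3 marks are confined to late non-genic zones and NRRs", {
  gb <- build_genome(small_config(seed = 79, mark_frac = 1))
  truth <- gb$truth
  seg <- truth$segments
  hosts <- seg[(seg$kind == "IZ" & seg$as_type == "non_genic") |
                 seg$kind == "NRR", , drop = FALSE]
  for (i in seq_len(nrow(truth$marks))) {
    hit <- any(hosts$chrom == truth$marks$chrom[i] &
                 hosts$start <= truth$marks$start[i] &
                 hosts$end >= truth$marks$end[i])
    expect_true(hit)
  }
})
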