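# Synthetic genomes with planted replication architecture, transcription
# and ChIP enrichment. The generator is the package's ground truth: every
# downstream stage (RFD, segmentation, constant-RFD calls, RT domains,
# ChIP normalisation, classification, aggregates) can be scored against
# the planted structure.
#
# The noise-free RFD profile is a sum of logistic transitions: each
# initiation zone (IZ) of efficiency e contributes an ascending step of
# height 2e (the profile rises from -e to +e across the zone); termination
# is modelled by descending steps either as a single central termination
# zone (TZ) between nearby IZs or as a pair of steps through an
# intermediate +0.3 plateau when IZs are far apart (so that plateaus of
# high-efficiency IZs never masquerade as unidirectionally replicating
# regions). URRs are plateaus at +/-0.9 and NRRs at 0, each isolated by
# constant guard shoulders that keep the constant-RFD calls congruent
# with the planted spans and keep every ascending step outside IZs below
# the 0.5 RFD-shift filter.

#' Configuration for the synthetic-genome generator
#'
#' Defaults describe the study conditions the package is validated under:
#' one 50-Mb chromosome at 1-kb bins with 30 planted IZs of efficiencies
#' spanning 0.3-1, OK-seq depth 100 fragments per bin, two URRs and two
#' NRRs, and genic IZs grouped into early-replicating blocks.
#'
#' @param seed Root seed; all generator randomness derives from it.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param bin_width Fine bin width in bp (OK-seq and ChIP simulation).
#' @param rt_bin_width Replication-timing bin width in bp.
#' @param n_iz Planted IZs per chromosome.
#' @param iz_width_range IZ width range in bp.
#' @param iz_efficiencies Efficiencies of the planted IZs; `NULL` spreads
#'   them evenly over \[0.3, 1\].
#' @param frac_type1,frac_type2 Fractions of IZs flanked by expressed
#'   genes on both / exactly one side(s); the remainder is non-genic.
#' @param n_urr,urr_width,urr_level URR count, width (bp) and |RFD| level.
#' @param n_nrr,nrr_width NRR count and width (bp).
#' @param tz_width Width of termination transitions in bp.
#' @param shoulder_width Guard-shoulder width flanking URRs/NRRs in bp.
#' @param early_radius Half-width of the early-timing field around early
#'   IZ centres in bp.
#' @param n_background_genes Background genes per chromosome.
#' @param gene_length_range Background gene length range in bp.
#' @param p_silent Probability that a background gene is untranscribed.
#' @param mark_frac Fraction of late non-genic IZs carrying H4K20me3.
#' @param marks_per_nrr H4K20me3 sub-intervals planted per NRR.
#' @param mark_width Width of NRR mark intervals in bp.
#' @param okseq_depth Mean Okazaki fragments per fine bin.
#' @param chip_depth Mean ChIP reads per fine bin.
#' @param rna_depth Expected reads per TPM-kb unit for gene counts.
#' @param acc_rt,acc_tss Accessibility amplitudes: early-timing elevation
#'   and active-TSS elevation of the input/chromatin accessibility field.
#' @param chip_params Optional data frame overriding [chip_factor_params()].
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1, n_chrom = 1, chrom_length = 5e7,
                       bin_width = 1000, rt_bin_width = 10000,
                       n_iz = 30, iz_width_range = c(30000, 60000),
                       iz_efficiencies = NULL, frac_type1 = 0.4,
                       frac_type2 = 0.35, n_urr = 2, urr_width = 4e5,
                       urr_level = 0.9, n_nrr = 2, nrr_width = 7e5,
                       tz_width = 40000, shoulder_width = 120000,
                       early_radius = 4e5, n_background_genes = 220,
                       gene_length_range = c(15000, 80000),
                       p_silent = 0.45, mark_frac = 0.5, marks_per_nrr = 3,
                       mark_width = 50000, okseq_depth = 100,
                       chip_depth = 20, rna_depth = 0.3, acc_rt = 0.3,
                       acc_tss = 0.5, chip_params = NULL) {
  cfg <- as.list(environment())
  fail_unless(chrom_length > 0 && bin_width >= 1 && n_chrom >= 1,
              "genome dimensions must be positive")
  fail_unless(rt_bin_width %% bin_width == 0,
              "rt_bin_width must be a multiple of bin_width")
  fail_unless(frac_type1 + frac_type2 <= 1, "type fractions exceed 1")
  if (is.null(cfg$iz_efficiencies)) {
    cfg$iz_efficiencies <- seq(0.3, 1, length.out = max(n_iz, 2))[
      seq_len(n_iz)]
  }
  fail_unless(all(cfg$iz_efficiencies > 0 & cfg$iz_efficiencies <= 1),
              "efficiencies must lie in (0, 1]")
  if (is.null(cfg$chip_params)) cfg$chip_params <- chip_factor_params()
  structure(cfg, class = "SimConfig")
}

#' Default per-factor ChIP enrichment parameters
#'
#' `rt_ratio_g1` / `rt_ratio_sg2m` are the early/late mean density ratios
#' per cell-cycle phase, `depletion` the multiplicative gene-body factor
#' on actively transcribed genes, `tss_amp` the amplitude of the Gaussian
#' TSS peak (half-width about 2 kb), `mark_boost` the multiplier inside
#' H4K20me3-marked intervals, and `self_enrich` the enrichment of the
#' profiled mark itself in marked intervals.
#'
#' @return A data frame keyed by `factor`.
#' @export
chip_factor_params <- function() {
  data.frame(
    factor = c("Orc2", "Orc3", "Mcm3", "Mcm7", "H4K20me1", "H4K20me3",
               "input"),
    rt_ratio_g1 = c(1.40, 1.47, 1.15, 1.19, 1.00, 1.10, 1.00),
    rt_ratio_sg2m = c(1.18, 1.24, 0.93, 1.02, 1.00, 1.10, 1.00),
    depletion = c(0.80, 0.80, 0.60, 0.70, 1.00, 1.00, 1.00),
    tss_amp = c(2.0, 2.0, 1.3, 1.3, 1.0, 1.0, 1.0),
    mark_boost = c(1.5, 1.5, 1.5, 1.5, 1.0, 1.0, 1.0),
    self_enrich = c(1, 1, 1, 1, 1, 4, 1),
    stringsAsFactors = FALSE)
}

# Rejection-sample n positions (starts) of given widths inside [lo, hi)
# avoiding forbidden intervals (with clearance) and keeping min_gap
# between placed items. Returns sorted starts or errors.
place_positions <- function(n, widths, lo, hi, forbidden = NULL,
                            clearance = 0, min_gap = 0, max_try = 5000,
                            what = "feature") {
  starts <- numeric(0); ends <- numeric(0)
  for (i in seq_len(n)) {
    w <- widths[i]
    ok <- FALSE
    for (t in seq_len(max_try)) {
      s <- floor(stats::runif(1, lo, hi - w))
      e <- s + w
      if (!is.null(forbidden) && nrow(forbidden) &&
          any(forbidden$start - clearance < e &
              forbidden$end + clearance > s)) next
      if (length(starts) &&
          any(starts - min_gap < e & ends + min_gap > s)) next
      ok <- TRUE
      break
    }
    fail_unless(ok, "cannot place %s %d of %d: density too high", what, i, n)
    starts <- c(starts, s); ends <- c(ends, e)
  }
  ord <- order(starts)
  data.frame(start = starts[ord], end = ends[ord])
}

#' Build a synthetic genome with planted replication architecture
#'
#' Places URRs, NRRs and IZs per chromosome, assigns IZ types (type 1 /
#' type 2 / non-genic) at the configured fractions by planting expressed
#' flanking genes, fills the remaining space with background genes of
#' zero-inflated log-normal expression, derives a smooth replication
#' timing field that is early around genic IZs and late elsewhere, and
#' marks a subset of late non-genic IZs plus NRR sub-intervals with
#' H4K20me3. Gene TPMs are scaled to sum to 1e6 and read counts drawn so
#' the TPM computation can be exercised end to end. Fully deterministic
#' given the config (which carries the seed).
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (gene table) and `truth` (class
#'   `SyntheticTruth`: `chrom_sizes`, `segments`, `genes`, `marks`, `rt`,
#'   `config`).
#' @export
build_genome <- function(config = sim_config()) {
  fail_unless(inherits(config, "SimConfig"), "config must be a SimConfig")
  with_seed(seed_stream(config$seed, "layout"), build_genome_impl(config))
}

build_genome_impl <- function(config) {
  w <- config$bin_width
  chrom_sizes <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                                 paste0("chr", seq_len(config$n_chrom)))
  seg_rows <- list(); gene_rows <- list(); mark_rows <- list()
  grid <- function(x) round(x / config$rt_bin_width) * config$rt_bin_width
  for (ch in names(chrom_sizes)) {
    L <- chrom_sizes[[ch]]
    margin <- 1.2e6
    # constant features first: URRs then NRRs, mutually cleared
    const <- data.frame(start = numeric(), end = numeric())
    reserve <- config$shoulder_width + 2e5
    cw <- c(rep(config$urr_width, config$n_urr),
            rep(config$nrr_width, config$n_nrr))
    ckind <- c(rep("URR", config$n_urr), rep("NRR", config$n_nrr))
    if (length(cw)) {
      const <- place_positions(length(cw), cw, margin, L - margin,
                               min_gap = 2 * reserve + 6e5,
                               what = "constant-RFD region")
      # place_positions sorts by start; recover each kind by its width
      used <- rep(FALSE, length(cw))
      const$kind <- vapply(seq_len(nrow(const)), function(i) {
        j <- which(!used & cw == const$end[i] - const$start[i])[1]
        used[j] <<- TRUE
        ckind[j]
      }, character(1))
      widths <- const$end - const$start
      const$start <- grid(const$start)
      const$end <- const$start + widths
    } else const$kind <- character(0)
    # IZs avoid constants (incl. shoulders) and chromosome ends
    n_iz <- config$n_iz
    iz_w <- round(stats::runif(n_iz, config$iz_width_range[1],
                               config$iz_width_range[2]) / w) * w
    iz <- place_positions(n_iz, iz_w, margin, L - margin,
                          forbidden = const, clearance = reserve + 2e5,
                          min_gap = 4.5e5, what = "initiation zone")
    widths <- iz$end - iz$start  # already multiples of the bin width
    iz$start <- round(iz$start / w) * w
    iz$end <- iz$start + widths
    eff <- config$iz_efficiencies
    n_t1 <- round(config$frac_type1 * n_iz)
    n_t2 <- round(config$frac_type2 * n_iz)
    n_ng <- n_iz - n_t1 - n_t2
    types <- sample(c(rep("type1", n_t1), rep("type2", n_t2),
                      rep("non_genic", n_ng)))
    eff <- sample(eff)
    iz$efficiency <- eff
    iz$as_type <- types
    iz$rt_class <- ifelse(types == "non_genic", "late", "early")
    iz$marked <- FALSE
    late_ng <- which(iz$as_type == "non_genic")
    if (length(late_ng) && config$mark_frac > 0) {
      n_marked <- ceiling(config$mark_frac * length(late_ng))
      iz$marked[sample(late_ng, n_marked)] <- TRUE
    }
    seg_rows[[length(seg_rows) + 1]] <- data.frame(
      chrom = ch, start = iz$start, end = iz$end, kind = "IZ",
      efficiency = iz$efficiency, rt_class = iz$rt_class,
      as_type = iz$as_type, marked = iz$marked, level = NA_real_,
      stringsAsFactors = FALSE)
    if (nrow(const)) {
      # URR polarity alternates along the chromosome so unidirectional
      # stretches do not bias the genome-wide fork balance
      urr_sign <- rep(1, nrow(const))
      is_urr <- const$kind == "URR"
      urr_sign[is_urr] <- (-1)^(seq_len(sum(is_urr)) - 1)
      seg_rows[[length(seg_rows) + 1]] <- data.frame(
        chrom = ch, start = const$start, end = const$end,
        kind = const$kind,
        efficiency = NA_real_, rt_class = "late", as_type = NA_character_,
        marked = FALSE,
        level = ifelse(is_urr, config$urr_level * urr_sign, 0),
        stringsAsFactors = FALSE)
    }
    # marks: flagged IZ spans plus random NRR sub-intervals
    mk <- iz[iz$marked, c("start", "end"), drop = FALSE]
    nrrs <- const[const$kind == "NRR", , drop = FALSE]
    for (i in seq_len(nrow(nrrs))) {
      for (k in seq_len(config$marks_per_nrr)) {
        s <- grid(stats::runif(1, nrrs$start[i],
                               nrrs$end[i] - config$mark_width))
        mk <- rbind(mk, data.frame(start = s, end = s + config$mark_width))
      }
    }
    if (nrow(mk)) {
      mark_rows[[length(mark_rows) + 1]] <-
        interval_set(rep(ch, nrow(mk)), mk$start, mk$end)
    }
    # genes: expressed flank genes realise the IZ types
    genes <- data.frame(start = numeric(), end = numeric(),
                        role = character(), stringsAsFactors = FALSE)
    flank_gene <- function(border, side) {
      len <- round(stats::runif(1, 35000, 70000) / 1000) * 1000
      gap <- round(stats::runif(1, 3000, 12000) / 1000) * 1000
      if (side == "left") {
        data.frame(start = border - gap - len, end = border - gap)
      } else {
        data.frame(start = border + gap, end = border + gap + len)
      }
    }
    for (i in seq_len(n_iz)) {
      sides <- switch(iz$as_type[i],
                      type1 = c("left", "right"),
                      type2 = sample(c("left", "right"), 1),
                      character(0))
      for (sd_ in sides) {
        b <- if (sd_ == "left") iz$start[i] else iz$end[i]
        g <- flank_gene(b, sd_)
        g$role <- "flank"
        genes <- rbind(genes, g)
      }
    }
    # background genes keep clear of IZs (+/- 45 kb), constants and
    # existing genes (16 kb isolation so most genes suit metaprofiles)
    occupied <- rbind(
      data.frame(start = iz$start - 45000, end = iz$end + 45000),
      data.frame(start = const$start - config$shoulder_width,
                 end = const$end + config$shoulder_width),
      if (nrow(genes)) genes[, c("start", "end")] else NULL)
    placed <- 0
    for (i in seq_len(config$n_background_genes)) {
      len <- round(stats::runif(1, config$gene_length_range[1],
                                config$gene_length_range[2]) / 1000) * 1000
      done <- FALSE
      for (t in 1:200) {
        s <- floor(stats::runif(1, margin / 2, L - margin / 2 - len))
        e <- s + len
        if (any(occupied$start - 16000 < e & occupied$end + 16000 > s))
          next
        genes <- rbind(genes,
                       data.frame(start = s, end = e, role = "background"))
        occupied <- rbind(occupied, data.frame(start = s, end = e))
        done <- TRUE
        break
      }
      if (done) placed <- placed + 1
    }
    fail_unless(placed >= config$n_background_genes / 2,
                "gene density too high: placed only %d of %d background genes",
                placed, config$n_background_genes)
    genes$chrom <- rep(ch, nrow(genes))
    gene_rows[[length(gene_rows) + 1]] <- genes
  }
  segments <- do.call(rbind, seg_rows)
  genes <- do.call(rbind, gene_rows)
  marks <- if (length(mark_rows)) do.call(rbind, mark_rows) else
    interval_set()
  # expression: flank genes expressed, background zero-inflated
  # log-normal; scale so TPMs sum to 1e6
  n_g <- nrow(genes)
  raw <- numeric(n_g)
  bg <- genes$role == "background"
  silent <- bg & stats::runif(n_g) < config$p_silent
  raw[bg] <- exp(stats::rnorm(sum(bg), 0, 2.4))
  raw[silent] <- 0
  raw[!bg] <- exp(stats::rnorm(sum(!bg), log(5), 0.8))
  tpm <- if (sum(raw) > 0) raw * 1e6 / sum(raw) else raw
  # keep flank genes safely expressed (TPM > 3) after scaling
  tpm[!bg] <- pmax(tpm[!bg], 5)
  genes$strand <- sample(c("+", "-"), n_g, replace = TRUE)
  genes$exonic_length_kb <- (genes$end - genes$start) / 1000
  genes$tpm <- tpm
  genes$read_count <- stats::rpois(
    n_g, config$rna_depth * genes$tpm * genes$exonic_length_kb / 100)
  genes$gene_id <- sprintf("G%04d", seq_len(n_g))
  genes <- genes[order(genes$chrom, genes$start),
                 c("gene_id", "chrom", "start", "end", "strand",
                   "exonic_length_kb", "read_count", "tpm", "role")]
  rownames(genes) <- NULL
  rt <- build_rt_track(segments, chrom_sizes, config)
  truth <- structure(
    list(chrom_sizes = chrom_sizes, segments = segments, genes = genes,
         marks = marks, rt = rt, config = config),
    class = "SyntheticTruth")
  list(genes = genes, truth = truth)
}

# Smooth replication-timing field at rt_bin_width: +2.5 within
# early_radius of early IZ centres, -3 elsewhere, Gaussian-smoothed with
# a 150-kb kernel.
build_rt_track <- function(segments, chrom_sizes, config) {
  wrt <- config$rt_bin_width
  vals <- list()
  for (ch in names(chrom_sizes)) {
    nb <- n_bins(chrom_sizes[[ch]], wrt)
    x <- (seq_len(nb) - 0.5) * wrt
    v <- rep(-3, nb)
    iz <- segments[segments$chrom == ch & segments$kind == "IZ" &
                     segments$rt_class == "early", , drop = FALSE]
    for (i in seq_len(nrow(iz))) {
      c_i <- (iz$start[i] + iz$end[i]) / 2
      v[abs(x - c_i) <= config$early_radius] <- 2.5
    }
    # small deterministic undulation: real timing tracks are never
    # exactly flat, and downstream timing deciles need a continuous
    # distribution; the amplitude keeps plateaus past the domain
    # thresholds
    v <- v + 0.15 * sin(2 * pi * x / 1.3e6)
    sigma_bins <- 150000 / wrt
    half <- ceiling(4 * sigma_bins)
    kern <- stats::dnorm((-half):half, 0, sigma_bins)
    kern <- kern / sum(kern)
    pad <- c(rep(v[1], half), v, rep(v[nb], half))
    sm <- stats::filter(pad, kern, method = "convolution", sides = 2)
    vals[[ch]] <- as.numeric(sm[(half + 1):(half + nb)])
  }
  binned_track(vals, wrt, chrom_sizes)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(
    "SyntheticTruth: %d chromosome(s), %d planted segments, %d genes\n",
    length(x$chrom_sizes), nrow(x$segments), nrow(x$genes)))
  print(table(x$segments$kind))
  invisible(x)
}

# Deterministic plan of logistic transitions and constant pieces for one
# chromosome. Returns list(constants = df(start, end, value),
# steps = df(center, height, scale), baseline).
plan_rfd_chrom <- function(segments, L, config) {
  iz <- segments[segments$kind == "IZ", , drop = FALSE]
  const <- segments[segments$kind %in% c("URR", "NRR"), , drop = FALSE]
  sw <- config$shoulder_width
  tzs <- config$tz_width / 6
  lead <- 150000  # distance from IZ border to its lead/termination step
  constants <- data.frame(start = numeric(), end = numeric(),
                          value = numeric())
  add_const <- function(s, e, v) {
    constants <<- rbind(constants, data.frame(start = s, end = e,
                                              value = v))
  }
  for (i in seq_len(nrow(const))) {
    lvl <- const$level[i]
    # shoulder plateaus break constant-RFD runs right at the planted
    # edges while keeping every junction descending or ascending by
    # less than the 0.5 shift filter
    shoulder_val <- if (const$kind[i] == "URR") 0.5 * sign(lvl + 1e-9)
      else 0.3
    add_const(const$start[i] - sw, const$start[i], shoulder_val)
    add_const(const$start[i], const$end[i], lvl)
    add_const(const$end[i], const$end[i] + sw, shoulder_val)
  }
  # sectors: gaps between constant blocks (merged) and chromosome ends
  if (nrow(constants)) {
    cb <- constants[order(constants$start), , drop = FALSE]
    blocks <- merge_plain(cb$start, cb$end)
    sec_start <- c(0, blocks$end)
    sec_end <- c(blocks$start, L)
  } else {
    sec_start <- 0; sec_end <- L
  }
  steps <- data.frame(center = numeric(), height = numeric(),
                      scale = numeric())
  add_step <- function(c_, h, s_) {
    steps <<- rbind(steps, data.frame(center = c_, height = h, scale = s_))
  }
  sectors <- data.frame(start = sec_start, end = sec_end,
                        baseline = NA_real_)
  no_features <- nrow(iz) == 0 && nrow(const) == 0
  for (k in seq_len(nrow(sectors))) {
    s0 <- sectors$start[k]; s1 <- sectors$end[k]
    if (s1 <= s0) { sectors$baseline[k] <- 0; next }
    in_iz <- iz[iz$start >= s0 & iz$end <= s1, , drop = FALSE]
    in_iz <- in_iz[order(in_iz$start), , drop = FALSE]
    if (!nrow(in_iz)) {
      if (no_features) {  # featureless chromosomes are fork-balanced
        sectors$baseline[k] <- 0
        next
      }
      # IZ-free sectors bridge the flanking shoulder levels; unequal
      # levels are laddered through a midpoint plateau of at most
      # 300 kb so every jump stays below the 0.5 shift filter and no
      # intermediate plateau is long enough to mimic an NRR
      vl <- constants$value[abs(constants$end - s0) < 1][1]
      vr <- constants$value[abs(constants$start - s1) < 1][1]
      if (is.na(vl) && is.na(vr)) {
        sectors$baseline[k] <- 0.3
      } else if (is.na(vl) || is.na(vr) ||
                 isTRUE(all.equal(vl, vr))) {
        sectors$baseline[k] <- if (is.na(vl)) vr else vl
      } else {
        sectors$baseline[k] <- vl
        len <- s1 - s0
        step_w <- min(3e5, len / 3)
        add_const(s1 - 2 * step_w, s1 - step_w, (vl + vr) / 2)
        add_const(s1 - step_w, s1, vr)
      }
      next
    }
    sectors$baseline[k] <- -0.3
    e <- in_iz$efficiency
    # lead-in: -0.3 down to -e1 ahead of the first IZ
    add_step(max(in_iz$start[1] - lead, s0 + 60000), -e[1] + 0.3, tzs)
    for (i in seq_len(nrow(in_iz))) {
      c_i <- (in_iz$start[i] + in_iz$end[i]) / 2
      s_i <- (in_iz$end[i] - in_iz$start[i]) / 6
      add_step(c_i, 2 * e[i], s_i)
      if (i < nrow(in_iz)) {
        gap <- in_iz$start[i + 1] - in_iz$end[i]
        if (gap <= 6e5) {
          add_step((in_iz$end[i] + in_iz$start[i + 1]) / 2,
                   -(e[i] + e[i + 1]), tzs)
        } else {
          # wide gaps descend through an intermediate plateau whose
          # polarity alternates so the genome stays fork-balanced
          # (mean RFD near 0); both sub-steps descend or ascend by
          # no more than 0.3 - min efficiency
          m <- 0.3 * (-1)^(i %% 2)
          add_step(in_iz$end[i] + lead, m - e[i], tzs)
          add_step(in_iz$start[i + 1] - lead, -e[i + 1] - m, tzs)
        }
      }
    }
    # lead-out: +e_last down to +0.3 after the last IZ
    add_step(min(in_iz$end[nrow(in_iz)] + lead, s1 - 60000),
             0.3 - e[nrow(in_iz)], tzs)
  }
  list(constants = constants, steps = steps, sectors = sectors)
}

# Merge touching/overlapping plain numeric intervals.
merge_plain <- function(start, end) {
  ord <- order(start)
  start <- start[ord]; end <- end[ord]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Noise-free RFD track of a planted architecture
#'
#' Deterministic evaluation of the planted replication program at fine-bin
#' centres: logistic ascending ramps of height `2 e` across IZs,
#' descending termination transitions between them, URR plateaus at the
#' configured level, NRR plateaus at 0, guard shoulders and lead plateaus
#' at |0.3|-|0.5| elsewhere. Values lie in \[-1, 1\].
#'
#' @param truth A `SyntheticTruth`.
#' @return A [binned_track()] at the config's fine bin width.
#' @export
true_rfd <- function(truth) {
  config <- truth$config
  w <- config$bin_width
  vals <- list()
  for (ch in names(truth$chrom_sizes)) {
    L <- truth$chrom_sizes[[ch]]
    nb <- n_bins(L, w)
    x <- (seq_len(nb) - 0.5) * w
    plan <- plan_rfd_chrom(
      truth$segments[truth$segments$chrom == ch, , drop = FALSE], L,
      config)
    v <- rep(NA_real_, nb)
    for (k in seq_len(nrow(plan$sectors))) {
      sel <- x >= plan$sectors$start[k] & x < plan$sectors$end[k]
      if (!any(sel)) next
      vv <- rep(plan$sectors$baseline[k], sum(sel))
      xs <- x[sel]
      st <- plan$steps[plan$steps$center >= plan$sectors$start[k] &
                         plan$steps$center < plan$sectors$end[k], ,
                       drop = FALSE]
      for (i in seq_len(nrow(st))) {
        vv <- vv + st$height[i] /
          (1 + exp(-(xs - st$center[i]) / st$scale[i]))
      }
      v[sel] <- vv
    }
    for (i in seq_len(nrow(plan$constants))) {
      sel <- x >= plan$constants$start[i] & x < plan$constants$end[i]
      v[sel] <- plan$constants$value[i]
    }
    vals[[ch]] <- pmin(pmax(v, -1), 1)
  }
  binned_track(vals, w, truth$chrom_sizes)
}

#' Simulate stranded Okazaki-fragment counts
#'
#' Per fine bin, the total fragment count is Poisson(`depth`) and the
#' reverse-strand count Binomial(total, (1 + RFD_true) / 2); forward =
#' total - reverse. Bins with zero fragments yield missing RFD downstream.
#'
#' @param truth A `SyntheticTruth`.
#' @param depth Mean fragments per bin (default from the config).
#' @param seed Seed (default derived from the config seed).
#' @return A [stranded_bin_counts()].
#' @export
simulate_okseq <- function(truth, depth = NULL, seed = NULL) {
  config <- truth$config
  if (is.null(depth)) depth <- config$okseq_depth
  if (is.null(seed)) seed <- seed_stream(config$seed, "okseq")
  fail_unless(depth >= 0, "depth must be non-negative")
  rfd <- true_rfd(truth)
  with_seed(seed, {
    Rv <- list(); Fv <- list()
    for (ch in names(rfd$values)) {
      p <- (1 + rfd$values[[ch]]) / 2
      n <- stats::rpois(length(p), depth)
      r <- stats::rbinom(length(p), n, p)
      Rv[[ch]] <- r
      Fv[[ch]] <- n - r
    }
    stranded_bin_counts(Rv, Fv, config$bin_width, truth$chrom_sizes)
  })
}

# Clamped ramp mapping timing values onto [0, 1] between the late and
# early domain thresholds; drives the RT dependence of ChIP enrichment.
rt_ramp01 <- function(rt) pmin(pmax((rt + 2) / 3.6, 0), 1)

# Per-fine-bin accessibility: 1 + acc_rt * ramp(RT) + acc_tss * Gaussian
# bumps (sd 2 kb) at active TSSs.
accessibility_vec <- function(truth, ch, rt_fine) {
  config <- truth$config
  w <- config$bin_width
  nb <- n_bins(truth$chrom_sizes[[ch]], w)
  x <- (seq_len(nb) - 0.5) * w
  acc <- 1 + config$acc_rt * rt_ramp01(rt_fine)
  g <- truth$genes[truth$genes$chrom == ch & truth$genes$tpm > 3, ,
                   drop = FALSE]
  for (i in seq_len(nrow(g))) {
    tss <- if (g$strand[i] == "-") g$end[i] else g$start[i]
    nearby <- abs(x - tss) < 10000
    acc[nearby] <- acc[nearby] +
      config$acc_tss * exp(-(x[nearby] - tss)^2 / (2 * 2000^2))
  }
  acc
}

# Expand the 10-kb timing track to fine bins.
rt_fine_vec <- function(truth, ch) {
  config <- truth$config
  k <- config$rt_bin_width %/% config$bin_width
  nb <- n_bins(truth$chrom_sizes[[ch]], config$bin_width)
  rep(truth$rt$values[[ch]], each = k)[seq_len(nb)]
}

#' Simulate a ChIP count track for one factor
#'
#' Per-bin counts are Poisson with rate
#' `depth * accessibility * enrichment`, where enrichment multiplies a
#' replication-timing ramp interpolating the configured early/late ratio
#' (flattened for MCM in S-G2-M per the phase-specific ratios), a
#' gene-body depletion on actively transcribed genes (TPM > 3, ORC/MCM),
#' a Gaussian TSS peak at active TSSs, and an H4K20me3 boost within
#' marked intervals. The input factor carries accessibility only.
#'
#' @param truth A `SyntheticTruth`.
#' @param factor One of `"Orc2"`, `"Orc3"`, `"Mcm3"`, `"Mcm7"`,
#'   `"H4K20me1"`, `"H4K20me3"`, `"input"`.
#' @param phase `"G1"` or `"S-G2-M"`.
#' @param depth Mean reads per bin (default from the config).
#' @param seed Seed (default derived from the config seed).
#' @return A count [binned_track()] at the fine bin width.
#' @export
simulate_chip <- function(truth, factor, phase = c("G1", "S-G2-M"),
                          depth = NULL, seed = NULL) {
  phase <- match.arg(phase)
  config <- truth$config
  pars <- config$chip_params
  fail_unless(factor %in% pars$factor, "unknown factor %s", factor)
  p <- pars[pars$factor == factor, ]
  if (is.null(depth)) depth <- config$chip_depth
  if (is.null(seed))
    seed <- seed_stream(config$seed, paste0("chip_", factor, "_", phase))
  ratio <- if (phase == "G1") p$rt_ratio_g1 else p$rt_ratio_sg2m
  with_seed(seed, {
    vals <- list()
    for (ch in names(truth$chrom_sizes)) {
      w <- config$bin_width
      nb <- n_bins(truth$chrom_sizes[[ch]], w)
      x <- (seq_len(nb) - 0.5) * w
      rtf <- rt_fine_vec(truth, ch)
      acc <- accessibility_vec(truth, ch, rtf)
      enrich <- rep(1, nb)
      if (factor != "input") {
        enrich <- enrich * (1 + (ratio - 1) * rt_ramp01(rtf))
        if (p$depletion != 1) {
          g <- truth$genes[truth$genes$chrom == ch & truth$genes$tpm > 3, ,
                           drop = FALSE]
          for (i in seq_len(nrow(g))) {
            enrich[x >= g$start[i] & x < g$end[i]] <-
              enrich[x >= g$start[i] & x < g$end[i]] * p$depletion
          }
        }
        if (p$tss_amp != 1) {
          g <- truth$genes[truth$genes$chrom == ch & truth$genes$tpm > 3, ,
                           drop = FALSE]
          for (i in seq_len(nrow(g))) {
            tss <- if (g$strand[i] == "-") g$end[i] else g$start[i]
            nearby <- abs(x - tss) < 10000
            enrich[nearby] <- enrich[nearby] *
              (1 + (p$tss_amp - 1) *
                 exp(-(x[nearby] - tss)^2 / (2 * 2000^2)))
          }
        }
        boost <- max(p$mark_boost, p$self_enrich)
        if (boost != 1 && nrow(truth$marks)) {
          mk <- truth$marks[truth$marks$chrom == ch, , drop = FALSE]
          for (i in seq_len(nrow(mk))) {
            enrich[x >= mk$start[i] & x < mk$end[i]] <-
              enrich[x >= mk$start[i] & x < mk$end[i]] * boost
          }
        }
      }
      vals[[ch]] <- stats::rpois(nb, depth * acc * enrich)
    }
    binned_track(vals, config$bin_width, truth$chrom_sizes)
  })
}
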