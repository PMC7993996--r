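# Shared fixtures: small deterministic genomes and hand-built tracks.

# A small synthetic genome (12 Mb) that keeps unit tests fast; any
# sim_config argument can be overridden.
small_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(seed = seed, chrom_length = 12e6, n_iz = 8, n_urr = 1,
         n_nrr = 1, n_background_genes = 60),
    list(...))
  do.call(sim_config, args)
}

# Single-chromosome track from a plain vector.
vec_track <- function(v, bin_width = 1000, chrom = "chrT",
                      size = length(v) * bin_width) {
  binned_track(stats::setNames(list(v), chrom), bin_width,
               stats::setNames(size, chrom))
}

# Stranded counts from two plain vectors.
vec_counts <- function(R, F, bin_width = 1000, chrom = "chrT") {
  stranded_bin_counts(stats::setNames(list(R), chrom),
                      stats::setNames(list(F), chrom), bin_width,
                      stats::setNames(length(R) * bin_width, chrom))
}

# Minimal hand-built truth object: lets tests plant segments directly.
# segments: data.frame(chrom, start, end, kind, efficiency, rt_class,
# as_type, marked, level)
manual_truth <- function(segments, chrom_length = 10e6, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = 1)
  chroms <- unique(c(segments$chrom, "chr1"))
  sizes <- stats::setNames(rep(chrom_length, length(chroms)), chroms)
  rtv <- lapply(sizes, function(s)
    rep(0, n_bins(s, config$rt_bin_width)))
  structure(list(chrom_sizes = sizes, segments = segments,
                 genes = data.frame(gene_id = character(),
                                    chrom = character(),
                                    start = numeric(), end = numeric(),
                                    strand = character(),
                                    exonic_length_kb = numeric(),
                                    read_count = numeric(),
                                    tpm = numeric()),
                 marks = interval_set(),
                 rt = binned_track(rtv, config$rt_bin_width, sizes),
                 config = config),
            class = "SyntheticTruth")
}

plant_iz <- function(chrom, start, end, efficiency, rt_class = "early",
                     as_type = "non_genic") {
  data.frame(chrom = chrom, start = start, end = end, kind = "IZ",
             efficiency = efficiency, rt_class = rt_class,
             as_type = as_type, marked = FALSE, level = NA_real_,
             stringsAsFactors = FALSE)
}

plant_const <- function(chrom, start, end, kind, level) {
  data.frame(chrom = chrom, start = start, end = end, kind = kind,
             efficiency = NA_real_, rt_class = "late",
             as_type = NA_character_, marked = FALSE, level = level,
             stringsAsFactors = FALSE)
}
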