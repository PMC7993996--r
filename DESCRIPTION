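Package: repliseg
Title: Replication Program Analysis from Stranded Okazaki-Fragment and ChIP
    Bin Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse the DNA replication program of mammalian
    genomes from binned sequencing signals. Computes replication fork
    directionality (RFD) from stranded Okazaki-fragment counts, delineates
    replication initiation and termination zones as ascending and
    descending RFD segments via Gaussian second-derivative convexity,
    calls unidirectionally replicating and null-RFD regions and
    replication timing domains, normalises licensing-factor ChIP-seq bin
    counts with input correction, classifies initiation zones by
    transcriptional context and histone marks, builds locus-aligned
    aggregate profiles and replication-timing decile histograms, and
    provides interval-shuffling null models. A fully deterministic
    synthetic-genome generator with planted replication architecture,
    transcription and ChIP enrichment supplies ground truth for every
    stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
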