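Package: ribopause
Title: Codon-Level Ribosome Pause-Score Analysis for Bacterial Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for codon-resolution analysis of bacterial ribosome
    profiling data. Footprints are assigned to the ribosomal P-site codon by
    the 3'-end rule (the 15th nucleotide from the 3' terminus), accumulated
    into per-gene per-codon count tables, and converted to pause scores (reads
    at a codon divided by the gene's average read density). The package
    implements the gene density filter, edge-codon exclusion, replicate
    averaging, differential pause calling between strains, tripeptide motif
    aggregation over all 8,000 tripeptides in P-site- and E-site-centered
    framings, weighted pause-context sequence logos, and per-gene pause
    profiles. A footprint simulator with planted polyproline stall sites and
    ribosome queuing provides ground-truth data so the whole pipeline can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
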