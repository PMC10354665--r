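Package: eccprofiler
Title: Identification and Characterization of Extrachromosomal Circular DNA
    from Split-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects extrachromosomal circular DNA (eccDNA) from paired-end
    split-read alignments and characterizes the resulting call sets. Implements
    split-read junction calling with base-pair correction of junction shifts
    caused by flanking direct repeats, extraction of confident regions and
    assembly of multi-chromosomal-fragment circles, breakpoint and size
    profiling (size peaks, end-nucleotide composition, direct-repeat
    fractions), genomic annotation enrichment with double normalization and a
    seeded random-region null for enhancer overlap, gene-level abundance
    matrices from supportive split reads with recurrence analysis, and exact
    small-sample Wilcoxon tests. Ships a deterministic synthetic circle-
    sequencing simulator (rolling-circle and tagmentation chemistries) that
    writes SAM alignments with ground truth, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
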