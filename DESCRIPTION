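Package: peakshift
Title: Two-Condition ChIP-Seq Peak Redistribution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the redistribution of a chromatin mark
    (such as the histone variant H2A.Z) between two conditions from called
    ChIP-seq peaks, replicate coverage tracks and per-region fragment
    counts. Partitions two-condition peak sets into shared and
    condition-specific subsets, classifies shared peaks as broader-and-higher
    or narrower-and-lower from width and 1x-normalized signal-intensity
    changes, tests differential occupancy with an exact permutation test on
    log CPM, annotates regions as promoter or enhancer by distance to the
    transcription start site, builds genome-wide promoter lists and
    TSS-centred signal matrices, integrates differential-expression calls,
    and ships a seeded synthetic-data generator with full truth tables so
    every stage is testable without external downloads. All interval tables
    are plain tibbles (0-based half-open coordinates) designed for use with
    the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
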