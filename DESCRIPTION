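Package: translatomics
Title: Transcriptome and Translatome Analysis of Polysome-Profiling Microarray Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for combined transcriptome/translatome
    analysis of two-channel microarray polysome-profiling experiments, as used to
    study the bacterial heat-shock response. Builds normalized gene expression
    matrices from probe-level two-channel intensities (log-ratio formation with
    negative-signal handling, per-array median centering, batched between-array
    scale normalization, probe-to-gene averaging), tests for differential
    transcript abundance and translational efficiency with a rank-products
    permutation statistic (percentage-of-false-positives estimation), classifies
    genes into transcriptional/translational response groups, partitions
    monosome- versus polysome-associated transcripts, and characterizes the
    sequence composition of translationally enhanced gene sets (protein length,
    amino-acid usage, G+C windows and positional profiles, relative synonymous
    codon usage, start/stop codon choice) against resampled random-set null
    distributions. Includes a ground-truthed synthetic-data generator producing
    annotated genomes and replicated two-channel experiments with spiked
    regulation groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    seqinr,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
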