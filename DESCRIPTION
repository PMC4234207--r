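Package: tfbsbench
Title: Training, Calibration and Benchmarking of Transcription Factor
    Binding Site Models on ChIP-Seq Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to train and compare transcription factor binding site
    (TFBS) recognition models on ChIP-Seq peak sets. Implements pattern
    matching models trained on curated site alignments (a length-optimised
    mononucleotide position weight matrix and a SiteGA-style genetic
    algorithm discriminant over locally positioned dinucleotide
    frequencies), pattern discovery models trained on the peaks themselves
    (greedy gapless alignment maximising Kullback discrete information
    content in mono- and dinucleotide alphabets), calibration of per-model
    score thresholds from EMSA competition affinities, and benchmarking by
    recognized-peak fractions, ROC curves and Matthews correlation against
    Markov-shuffled backgrounds, including a chi-squared test for
    chance-expected non-overlapping co-detections in homotypic site
    clusters. A synthetic data generator with known ground truth supports
    the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
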