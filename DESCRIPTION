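Package: subteloscreen
Title: Subtelomeric Candidate Gene Screening from Telomeric Repeats and
    Differential ChIP-Seq Peaks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for identifying genes under telomeric
    control far from chromosome ends. Detects telomeric repeat arrays
    (TTAGGG motif) genome-wide and classifies them as terminal tracts or
    interstitial telomeric sequences (ITSs), compares ChIP-seq peak sets
    between two conditions to find peaks gained or lost upon modulation of
    a telomere-binding factor, associates peaks and ITSs to genes within a
    distance window (default 100 kb), intersects the resulting gene sets
    into a candidate report with Venn region counts, annotates each gene
    with its distance to the closest telomere, and quantifies expression
    and mitochondrial DNA content from qPCR Ct tables by the delta-delta-Ct
    method. A synthetic-data generator produces every input with known
    ground truth so the full screen runs and is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
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
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
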