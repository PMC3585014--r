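Package: chromfrag
Title: Fragment-Centric Analysis of Native MNase ChIP-Seq Chromatin Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fragment-centric analysis of paired-end MNase-based
    chromatin profiling data (native ChIP-seq and input chromatin): fragment
    size distributions with unit-area normalization and
    nucleosomal/supernucleosomal area-under-curve statistics, V-plot
    matrices of fragment midpoint distance versus fragment length around
    anchor sites, per-base-pair coverage and log2(IP/input) tracks with
    aggregate profiles, quintile grouping, ranked heatmaps and
    nucleosome-depleted-region correlation, sequence composition
    (position frequency matrices, A+T content) and trinucleotide DNA
    bendability scoring, plus a seed-deterministic synthetic chromatin
    simulator with full ground-truth bookkeeping and a config-driven
    pipeline reproducing all analyses end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
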