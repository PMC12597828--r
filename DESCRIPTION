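Package: taclr
Title: Domain Calling and Aggregate Analysis for Targeted Cohesin Loading Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for experiments that recruit the cohesin loader
    to ectopic TetO platforms and read out induced loop-extrusion trajectories.
    Implements per-viewpoint 4C normalization and smoothing, a two-state hidden
    Markov model with a run/merge/draft filter cascade that calls induced
    looping ("TACL") domains around each integration site, reference-peak
    scaling of ChIP-seq signal tracks, differential FLAG-peak classification,
    CTCF site stratification by strength and motif orientation relative to the
    TetO anchor, observed-over-expected Hi-C pileups with loop-strength,
    boundary-strength and TAD-density statistics, simplified negative-binomial
    differential testing with distance-grouped expression comparisons, and a
    seeded synthetic-data generator that plants ground-truth domains for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
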