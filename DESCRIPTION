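Package: orfoverlap
Title: Design and Evolutionary Analysis of Engineered Overlapping Reading Frames
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to engineer an overlapping reading frame inside an
    existing protein-coding sequence so that a downstream essential gene is
    translated from a ribosome-binding motif created within the gene to
    protect. Includes the sequence-design algorithm (Shine-Dalgarno motif
    creation by local brute force over synonymous codon variants, stop-codon
    and secondary-start clearing at configurable stringency), a Monte-Carlo
    simulator of the mutational protection conferred by an overlap together
    with its exact-expectation counterpart, an analytic Poisson model of
    circuit lifetime with multi-gene extensions, fluctuation-assay statistics
    (one-sided Mann-Whitney U, rank-biserial correlation, Jones median
    estimator of mutation numbers), batch genome screening summaries, and
    synthetic-data generators used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
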