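Package: sigiscan
Title: Discovery and Classification of SigI-Dependent Promoters in
    Cellulolytic Clostridia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding and classifying promoters recognized by the
    alternative sigma-I factors that regulate cellulosomal genes in
    cellulolytic clostridia. Implements a bipartite degenerate-motif scanner
    (homopolymeric A-tract -35 element, variable 12-15 nt spacer, CGHH-type
    -10 element), per-sigma position-frequency profiles with
    information-content and log-odds scoring, declarative
    region-of-specificity rules for regulon assignment and cross-talk
    detection, cross-species regulon transfer, in-silico saturation
    transversion mutagenesis of promoter windows, reporter-assay
    quantification (delta-FU with the not-detected rule and relative
    activity), and a seeded synthetic-genome generator with planted
    promoters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
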