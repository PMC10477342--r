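Package: wgdtrace
Title: Detection and Dating of Ancient Whole-Genome Duplications from
    Collinearity and Ks Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers paleopolyploidy from gene collinearity: homolog detection by
    affine-gap protein alignment, collinear block chaining by sparse dynamic
    programming, synteny depth ratios against an unduplicated outgroup,
    Nei-Gojobori (NG86) Ks estimation on codon alignments with block-median
    summaries, Gaussian-mixture peak fitting with BIC model selection,
    outgroup-anchored evolutionary-rate correction and molecular-clock dating of
    duplication events. Companion tools implement the LTR retrotransposon
    insertion clock (Kimura two-parameter divergence, T = K/2r) and per-pathway
    metabolite differential-abundance scores. A forward-time genome-evolution
    simulator with known truth (duplication ages, retention, synonymous rates)
    supports validation of the whole inference chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    igraph,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
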