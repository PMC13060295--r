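Package: kmerrate
Title: Repeat-Robust k-mer Based Estimation of Substitution Rates and ANI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free estimation of the per-position substitution rate
    between a sequence and its mutated counterpart from k-mer statistics.
    Implements presence-presence, presence-count and count-count estimators
    that remain accurate on highly repetitive sequences (e.g. centromeric
    alpha-satellite arrays) by counting the novel k-mers created by mutation
    rather than the shared ones, together with a Hamming-distance-1 bias
    correction, FracMinHash sketched variants, an exact-expectation oracle
    for the bias theorems, a substitution-process simulator, synthetic
    repeat-array generators, a replicate/error-grid evaluation harness, and
    an average nucleotide identity (ANI) application mode.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
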