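Package: pema
Title: Principal Elementary Mode Analysis of Metabolic Flux Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the subset of elementary flux modes (EMs) whose
    nonnegative combination best explains the variance of measured reaction
    flux data (the principal elementary modes), given a pre-specified
    universe of EM candidates. Implements EM pre-selection (ambiguity
    grouping and direction filtering), a greedy best-first deflation
    decomposition, and a branch-and-bound search over EM combinations with
    the greedy solution as incumbent, together with an uncentered PCA
    baseline, a synthetic flux-data generator with known ground truth, and
    a brute-force elementary-mode enumerator for small test networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
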