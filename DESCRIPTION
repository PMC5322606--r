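Package: phylomap
Title: Analytic Stochastic Character Mapping on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-branch expected dwelling times and expected
    numbers of state transitions for a discrete character evolving under a
    continuous-time Markov chain on rooted phylogenies, analytically
    (without stochastic simulation) via spectral decomposition of the
    instantaneous rate matrix. Batches the computation over posterior
    samples of trees, summarizes per-branch posterior distributions onto a
    user-supplied target topology by clade matching with 5%-step tonality
    binning, and renders painted phylograms. Also provides
    maximum-likelihood rate-matrix estimation under ER/SYM/ARD
    constraints, a pure-birth tree simulator, an exact character-history
    simulator, and an endpoint-conditioned path sampler used for
    validation against the analytic expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
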