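Package: swnet
Title: Small-World Network Analysis of Block-Design Working-Memory fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyzes load-wise functional brain networks from
    block-design working-memory fMRI node time series. Provides a synthetic
    cohort generator with planted graph structure (Gaussian graphical model
    sampling from Watts-Strogatz style precision matrices), zero-phase
    Butterworth band-pass filtering, block truncation and load-wise
    concatenation, shrinkage-regularized partial-correlation connectivity with
    Fisher r-to-z transformation, degree-uniform thresholding into binary
    undirected networks, graph metrics (clustering, characteristic path
    length, global and local efficiency), small-worldness against
    degree-preserving Markov-chain rewiring nulls, data-driven small-world
    regime search, and the group-by-load statistical stage (site correction,
    two-way ANOVA, per-observation t-tests with Benjamini-Hochberg FDR,
    load-contrast tests, behavior correlations, and head-motion summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    igraph,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
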