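Package: connectoperm
Title: Permutation Inference for Parcellated Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Group analysis of parcel-level resting-state functional
    connectomes. Builds per-subject Fisher-z connectivity matrices by
    Tikhonov (ridge) regularized partial correlation, thresholds them over
    a proportional-density grid into binary graphs, computes global and
    nodal graph-theory metrics with degree-preserving random-graph
    normalization and area-under-the-curve summaries, and performs
    covariate-adjusted group inference by Freedman-Lane permutation with
    max-statistic family-wise correction and Benjamini-Hochberg FDR.
    Includes the Network-Based Statistic for supra-threshold sub-network
    detection, Yeo 7-network within/between block connectivity comparison,
    covariate-controlled clinical correlation, and a seeded synthetic
    two-group cohort generator with block-structured covariance and
    injectable group effects for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    pracma,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
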