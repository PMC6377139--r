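Package: scnet
Title: Structural Covariance Network Analysis of Regional Gray-Matter Volumes
Version: 0.1.0
Authors@R:
    person("scnet", "developers", email = "scnet@example.org", role = c("aut", "cre"))
Description: Group-level graph-theoretical analysis of structural covariance
    networks built from regional gray-matter volumes. Constructs per-group
    Pearson association matrices over atlas regions, binarizes them across a
    connection-density sweep, computes global and nodal graph metrics
    (clustering coefficient, characteristic path length, betweenness
    centrality) with degree-preserving random-network normalization, assesses
    network resilience to random failure and betweenness-targeted attack, and
    compares groups by permutation tests on area-under-the-curve summaries
    with Benjamini-Hochberg false-discovery-rate control. Includes a
    synthetic two-group cohort generator with controllable inter-regional
    correlation structure, planted group differences and linear confounds,
    plus an optional front end extracting region volumes from modulated
    gray-matter probability maps and an integer-labeled parcellation atlas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
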