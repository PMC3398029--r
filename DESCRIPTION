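Package: rhmap
Title: Radiation Hybrid Panel Simulation and Map Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-genome radiation hybrid (RH) mapping in large
    plant genomes. Provides an S4 container for RH genotype panels
    (markers by hybrids, retained/absent/missing calls) built on
    SummarizedExperiment, readers and writers for delimited genotype
    matrices and the CarthaGene radiated-hybrid dialect, a generative
    simulator of RH panels (Poisson chromosome fragmentation with
    per-fragment retention and missing calls), two-point
    breakage/retention maximum-likelihood estimation with LOD scores and
    centiRay distances, linkage grouping, marker ordering by
    obligate-break minimization (exact dynamic programming and a 2-opt
    heuristic), multipoint map fitting with a hidden-state forward
    recursion over missing genotypes, and panel statistics: retention
    reports, Friedman homogeneity tests, map resolution arithmetic and
    marker-order concordance against reference orders.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
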