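Package: pathsgd
Title: Path-Guided Stochastic Gradient Descent Layout of Pangenome Variation Graphs
Version: 0.1.0
Authors@R: person("pathsgd", "developers", role = c("aut", "cre"),
    email = "pathsgd@example.org")
Description: Sorts (1D) and draws (2D) pangenome variation graphs by
    path-guided stochastic gradient descent. The genomes embedded in the
    graph as paths serve as a positional system: pairs of node ends are
    sampled along a path together with their nucleotide distance, and the
    layout is refined so that Euclidean distances match nucleotide
    distances, avoiding any all-pairs distance computation. Includes a
    GFA1 reader/writer, a path position index, Zipfian distance sampling
    with flip and cooling mechanics, layout quality metrics, seeded
    synthetic graph generators, SVG rendering, and a command line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
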