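Package: colodiff
Title: Differential Gene Co-Localization Analysis for Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects genes whose co-localization -- coordinated expression
    within local neighborhoods of the cell manifold -- differs between two
    single-cell RNA-seq conditions, without cell clustering or
    cross-condition integration. For each condition a gene graph is built
    from exact optimal-transport distances between gene expression
    distributions over a k-nearest-neighbor cell graph; the two graphs are
    contrasted with directional differential spectral operators, significant
    genes are called by local false discovery rate on eigenvector loadings,
    and called genes are assembled into co-localized modules with importance
    and per-cell activity scores. A negative-binomial simulation benchmark
    with neighborhood-confined injected signals and normalized-AUPRC
    evaluation is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
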