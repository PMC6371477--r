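Package: cellhash
Title: Scalable Cell Search for Single-Cell Expression Profiles via
    Locality-Sensitive Hashing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds compact, serializable databases of single-cell RNA-seq
    expression profiles and queries them for nearest-neighbor cells at high
    throughput.  Reference profiles are reduced by randomized singular value
    decomposition, hashed to short bit vectors with orthogonalized signed
    random projections, and indexed with multi-index hashing for exact
    k-nearest-neighbor search in Hamming space.  Utilities estimate cosine
    similarities from Hamming distances, transfer cell-type labels with
    consistency and Cohen's kappa evaluation, and detect differentially
    expressed genes between a query cell and the neighborhood of its matched
    database cell under a Poisson count model.  A synthetic-data generator
    produces clustered UMI count matrices with known labels, batch effects,
    and spiked genes for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
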