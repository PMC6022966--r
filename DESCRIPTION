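Package: ptdyn
Title: Pseudotime Dynamics of Single-Cell Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders single cells along a one-dimensional pseudotime from an
    ensemble of k-nearest-neighbour graphs, scores functional gene signatures
    per cell with the gene set Z-score (GSZ), smooths and normalizes the
    resulting pseudotime profiles with LOESS, tests pseudotime dependence of
    genes and gene sets with a spline-based likelihood-ratio test under
    Benjamini-Hochberg FDR control, and classifies the geometry of pairwise
    signature trajectories (divergent, orthogonal, parallel anti-correlated,
    switch-like, curved). Includes a synthetic expression-data generator with
    a known latent pseudotime and temporally patterned gene modules so every
    stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    Matrix,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
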