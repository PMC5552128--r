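Package: serpens
Title: Coupled Neural Oscillator Networks with a Snake-Like Body
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of Bonhoeffer-van der Pol oscillators wired by
    regular, small-world, scale-free or random graph topologies and coupled to a
    simplified planar snake-like musculoskeletal body, then analyses the
    movement patterns that emerge from the closed sensorimotor loop. Provides
    windowed joint-angle correlation features, Laplacian-eigenmap embedding,
    density-based clustering of movement patterns and Otsu-threshold stability
    classification; Kraskov-Stogbauer-Grassberger estimators of mutual
    information and transfer entropy for reconstructing directed information
    networks per movement pattern; infinite-relational-model block discovery;
    and weighted directed complex-network measures (clustering coefficient,
    inverse-weight shortest paths, node degree) applied to both the wired and
    the inferred information networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
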