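Package: basinflood
Title: Gradient-Basin Decomposition and Coarse-Grained Kinetics of RNA
    Energy Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact coarse-grained kinetics for discrete RNA
    secondary-structure energy landscapes.  Decomposes a landscape into
    gradient-basin macro-states, computes exact macro-state transition
    probabilities either by exhaustive (global) flooding or by a
    memory-efficient per-basin local flooding scheme, builds barrier trees
    with Arrhenius-type and merged transition models, and compares the
    resulting discrete-time Markov chains through first-passage times and
    Spearman rank correlation.  Includes a dependency-free base-pair
    energy model, an optional nearest-neighbor backend driven by the
    ViennaRNA command-line tools, explicit toy landscapes for exact
    hand-checkable computations, and deterministic fixture generators.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
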