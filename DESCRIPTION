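Package: hfnca
Title: Structure-Parameter Importance for Hyperfine Coupling Constants
    via Neighborhood Components Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps molecular-dynamics structural fluctuations of organic
    radicals (bond lengths, bond angles, dihedral angles) to hyperfine
    coupling constants using regularized neighborhood components analysis
    (NCA) for regression.  Reads multi-frame XYZ trajectories, extracts
    internal coordinates from first-frame bond connectivity, engineers
    standardized feature tables with trigonometric dihedral encoding, fits
    per-nucleus per-tensor-component NCA weights into importance matrices,
    and scores result quality with magnetic-equivalence symmetry
    descriptors.  A synthetic-data generator with sinusoidal
    internal-coordinate dynamics and planted feature dependencies replaces
    the quantum-chemistry stage for testing and method exploration.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
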