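Package: biofilmarch
Title: Quantitative Analysis and Mechanistic Simulation of Early Biofilm
    Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the three-dimensional architecture of
    early-stage bacterial biofilm microcolonies from tables of segmented
    single cells. Computes per-cell and emergent architectural properties
    (aspect ratio, local number density, local nematic order, surface area
    per volume), represents per-biofilm property distributions by
    Chebyshev polynomial coefficients of kernel density estimates, and
    compares biofilms and properties with a Chebyshev dissimilarity that
    upper-bounds the cumulative L1 distance between distributions.
    Includes silhouette-based redundancy reduction of correlated
    properties, principal component embedding of coefficient vectors
    (the biofilm architecture index), an overdamped agent-based model of
    growing, dividing rod-shaped cells on a substrate with steric
    repulsion, short-range adhesion, surface anchoring and anisotropic
    friction, parameter-scan fitting of the model to target biofilms by
    minimal dissimilarity, and a fast synthetic packing generator for
    testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    cluster,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
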