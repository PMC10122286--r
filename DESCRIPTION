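Package: myofibspat
Title: Spatial Analysis of Muscle Fiber-Type Distributions on Histological Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial arrangement of muscle fiber types on
    histological cross-sections from fiber centroid coordinates and type labels.
    Builds pruned Delaunay neighbor networks, alpha-shape section boundaries and
    clipped Voronoi tessellations; implements the mean cluster size permutation
    test, the unlike-neighbor-pairs (join count) test with analytic null moments,
    and the abnormally-grouped-fiber proportion; fits a binary Markov random
    field (autologistic) model by maximum pseudolikelihood with a permutation
    envelope for the interaction parameter; and fits penalized logistic and
    multinomial generalized additive models over thin-plate regression spline
    bases to map fiber-type probability surfaces. Includes a synthetic-section
    simulator (jittered lattices, Gibbs-sampled autologistic labels, smooth
    probability surfaces) for validation, batch fitting over section manifests,
    and group comparison of per-section model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    spatstat.geom,
    igraph,
    Matrix,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    mgcv,
    interp,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
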