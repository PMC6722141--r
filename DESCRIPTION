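Package: hgshrink
Title: Groupwise Image Registration by Hierarchical Graph Shrinkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unbiased groupwise registration of a population of co-registered
    3D scalar volumes. The population is clustered hierarchically with
    affinity propagation, a vertex-labeled graph set (intra-graphs within
    clusters, inter-graphs over cluster exemplars) is built on the image
    manifold, and all images are warped to an unbiased group center by
    dynamic graph shrinkage: stationary-velocity diffeomorphic demons
    supplies per-edge velocities, each vertex moves along its label-averaged
    velocity with an adaptive time step, and the per-step exponentials are
    composed into diffeomorphic deformation paths. A coarse-to-fine
    multi-resolution schedule accelerates convergence. Includes a synthetic
    phantom-population generator and Dice-overlap evaluation utilities.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
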