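Package: rfaseg
Title: Graph-Based Semi-Automatic Segmentation of Radiofrequency Ablation Zones in CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automatic 3D segmentation of radiofrequency-ablation (RFA)
    zones in CT volumes. Rays are cast from a user-defined seed point towards
    the vertices of a recursively refined polyhedron, nodes sampled along the
    rays are scored by their absolute intensity difference to an average
    ablation-zone value estimated around the seed, and a smoothness-constrained
    minimum s-t cut through the resulting flow network yields a closed lesion
    surface. The surface is voxelized into a solid binary mask and evaluated by
    Dice Similarity Coefficient and voxel volumetry. A synthetic CT phantom
    generator (dark lesion, bright rim, bright umbrella-shaped needle) provides
    ground-truth test data, and a brute-force optimal-surface oracle verifies
    the min-cut solver on small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    RNifti,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
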