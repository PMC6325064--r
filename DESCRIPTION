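Package: memtopo
Title: Brownian Motion and Apparent Anomalous Diffusion on Voxelized
    Membrane Surfaces
Version: 0.9.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates lateral diffusion on non-flat surfaces represented
    as graphs of 6-connected cubic voxel nodes, emulating the topography
    of biological membranes. Provides builders for flat, ridged (folded),
    pillar, invagination, bump and height-map derived surfaces;
    deterministic probability propagation of a lazy random walk and
    stochastic single-particle track sampling; planar (2D) and volume
    (3D) Euclidean distance maps together with the shortest
    within-surface (geodesic) distance computed by wave-front
    propagation; and mean squared displacement, diffusion coefficient and
    relative diffusion (D_rel) analyses that quantify how surface
    topography alone produces apparent super- and subdiffusion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
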