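Package: tpcfmesh
Title: Topographical Pair Correlation Functions for Curvature Fields on
    Triangular Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the topographical pair correlation function (TPCF),
    a spatial autocorrelation g(r) of per-vertex curvature metrics on
    triangular surface meshes, with distance r measured as the minimum
    number of mesh edges between vertices. Provides mesh input/output for
    STL, PLY, OBJ and OFF, quadric-error-metric decimation to a fixed
    element count, per-vertex principal curvature estimation by averaged
    shape operators, the derived Gaussian curvature, mean curvature,
    shape index and bending ratio fields, seeded generators for ideal and
    perturbed spheres and cylinders, and support-vector classification of
    mesh cohorts from TPCF area-under-curve and mean-radius features, as
    used in statistical shape analysis of aortic morphology.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    e1071,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
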