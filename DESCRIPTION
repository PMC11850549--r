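Package: epiVertex
Title: Vertex-Model Simulation of Homeostasis in Confined Epithelial Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional vertex model of a confluent epithelial
    monolayer in which a central patch of active (growing, dividing,
    ingressing) cells is embedded in passive tissue clamped to a rigid
    square boundary. The tissue is a half-edge polygonal tiling evolved by
    overdamped shape-energy dynamics with T1 (intercalation) and T2
    (extrusion) topological moves, stochastic size-dependent division and
    ingression, and centroidal-Voronoi initial conditions. Includes the
    full set of homeostasis observables: fractional cell count and area,
    cumulative division/ingression sums, homeostatic pressure, realised
    shape index, and neighbour-count distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deldir,
    optparse
Config/testthat/edition: 3
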