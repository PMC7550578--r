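Package: cortivertex
Title: Vertex-Model Simulation and Order-Parameter Analysis of Hair-Cell
    Patterning in the Organ of Corti
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-dimensional vertex model of the apical surface of the
    developing organ of Corti, in which global shear and local repulsion
    forces acting on hair cells drive a disordered salt-and-pepper mosaic
    of hair cells and supporting cells into an ordered checkerboard-like
    pattern. Implements the mechanical energy function (area elasticity,
    junctional line tension, perimeter contractility, steric hair-cell
    repulsion), external shear/compression forces, gradient-descent
    relaxation with T1 (intercalation) and T2 (delamination) transitions,
    lateral-inhibition initial patterning, staged simulation protocols
    (compaction, refinement, myosin-inhibition, laser ablation, and an
    adhesion-only alternative model), and an analysis suite for
    bond-orientational order (psi6 and its ellipse-rescaled variant),
    supporting-cell neighbor counts, area ratios, structure factors, row
    classification, intercalation rates and displacement profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
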