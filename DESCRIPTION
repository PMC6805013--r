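Package: serpentine
Title: Quantifying Cell Polarity, Edge Dynamics, and Bleb Reversals, with a
    Triangulated-Membrane Monte-Carlo Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cell polarity and membrane-protrusion dynamics
    from two-channel fluorescence time-lapse movies of motile cells: Otsu-based
    segmentation with distance-transform erosion, seeded propagation of a
    biosensor signal, centroid tracking with quality-control filters, mean
    squared displacement and persistence statistics, two complementary polarity
    scores (normalized centroid offset and angular intensity distribution),
    index-aligned boundary kymographs of edge velocity and edge fluorescence,
    lagged Pearson cross-correlation, and detection of travelling protrusions
    that reverse direction, compared against a rotation-randomized null.
    Includes a dynamically triangulated membrane Monte-Carlo simulator with
    curvature-coupled, self-attracting, force-exerting protein nodes, optional
    parallel-plate confinement, and tension and asphericity observables.
    A synthetic-data module generates movies, kymograph pairs, and vesicle
    meshes with known ground truth so every analysis stage can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    EBImage
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
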