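Package: sketchlayout
Title: Sketch-Guided Force-Directed Graph Layout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes force-directed graph layouts guided by a freehand
    sketch. A raster sketch is reduced to its topological skeleton by
    Zhang-Suen thinning, traced into polylines, simplified with a radial
    distance pass followed by Ramer-Douglas-Peucker, and assembled into an
    ordered chain of line segments. Graph nodes are mapped onto the chain
    (by a long-cycle heuristic for closed shapes or a two-pass BFS sweep
    otherwise) proportionally to segment lengths, direction-classified
    segments emit relative-placement and alignment constraints, and a
    constrained spring embedder with per-iteration constraint projection
    produces final positions, followed by a short displacement-capped
    unconstrained refinement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    png,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
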