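Package: ampscape
Title: Species-Agnostic Landscape Connectivity from Human-Modification Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for species-agnostic landscape-connectivity analysis with
    circuit theory. Builds degree-of-human-modification surfaces from binary
    human-footprint layers by the fuzzy algebraic sum, converts them into
    resistance rasters under alternative scaling functions and water-resistance
    levels, computes omnidirectional current-density maps by injecting current
    between boundary nodes of a buffered extent and solving the graph Laplacian,
    and quantifies map uncertainty across a factorial ensemble with z-score
    classifications, correlation and agreement matrices, and distance-based
    redundancy-analysis variance partitioning. Includes a synthetic-landscape
    generator so the full pipeline runs without external spatial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
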