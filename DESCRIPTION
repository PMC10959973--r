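Package: shoaldyn
Title: Collective States and Spatial Correlations in Small Fish Shoals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying collective behavior in small groups of fish
    (zebrafish-style shoals) as an interacting-agent system. Provides an
    agent-based simulator with overdamped constant-speed heading dynamics in
    a circular arena (wall avoidance, repulsion-attraction, alignment,
    far-field hydrodynamic coupling, field of view, and a variable-speed
    extension), analytic fixture generators (perfect school, perfect mill,
    random swarm, ideal gas), polarization and rotation order parameters
    with schooling/milling/swarming state classification, nearest-neighbor
    subgroup analysis, comoving-frame pair correlation maps with peak
    detection, radial pair correlations, three-fish bond-angle
    distributions, and observed versus Kirkwood-superposition three-body
    correlation maps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
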