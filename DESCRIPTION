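Package: ecoscape
Title: Ecological Security Patterns from Services, Sensitivity and
    Circuit-Theory Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs ecological security patterns on raster landscapes:
    ecosystem-service layers (habitat quality with distance-decayed threats,
    annual water yield, carbon storage), ecological-sensitivity layers
    (habitat and water sensitivity score overlays, CSLE soil loss), selection
    of ecological-source patches, a weighted multi-factor resistance surface,
    and connectivity analysis by least-cost corridors and circuit theory
    (current maps, current-flow centrality, pinch points, moving-window
    barrier detection, corridor prioritization). Includes a seeded synthetic
    landscape generator so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
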