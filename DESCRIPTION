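Package: paleocorridor
Title: Least-Cost-Path Dispersal Corridors and Climate-Stability Refugia
    on Raster Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models hominin dispersal corridors on georeferenced rasters.
    Builds slope-based movement-cost surfaces from digital elevation models
    (Horn finite differences), turns paleogeographic hypotheses (closed-basin
    sea-level stands, desert polygons, elevation suitability bands) into
    barrier masks, routes least-cost paths between archaeological sites with
    a deterministic Dijkstra solver on the 8-connected lattice with
    great-circle edge lengths, buffers settlement-potential corridors around
    routes, and computes temperature-change velocity between climate epochs
    to nominate climatically stable refugia. Ships a seeded synthetic
    landscape generator emulating a Caucasus-Caspian-Altai geography so the
    full pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
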