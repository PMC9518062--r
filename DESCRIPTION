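Package: espattern
Title: Ecological Security Pattern Construction on Raster Landscapes
Version: 0.1.0
Authors@R: person("ESP", "Maintainers", email = "esp@example.org", role = c("aut", "cre"))
Description: Tools for the importance-sensitivity-connectivity evaluation of
    regional ecological security and the downstream construction of ecological
    security patterns on gridded landscapes. Implements RUSLE soil-erosion
    estimation, certainty-factor geohazard susceptibility, InVEST-style habitat
    quality, Conefor-style landscape connectivity indices (IIC, PC, dIIC, dPC),
    land-use resistance surfaces with nightlight and elevation corrections,
    minimum-cumulative-resistance corridor extraction, and typed ecological
    node identification, together with a seeded synthetic mountainous-scene
    generator so that every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
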