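Package: slrmig
Title: Coupled Sea-Level-Rise and Human-Migration Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates how sea-level rise reshapes inter-county migration.
    A climate module partitions spatial zones into flooded (affected) and
    habitable (unaffected) portions at scheduled sea-level-rise increments;
    a migration module routes climate-forced migrants and business-as-usual
    migrants through separately parameterised spatial-interaction models
    (radiation, extended radiation, or a trainable neural scorer over
    population, distance and intervening-opportunity features); and an
    effects module classifies counties as directly or indirectly affected
    by comparing incoming migration against a no-flooding baseline. Includes
    a shock filter for detecting hurricane-displaced origin counties in
    year-pair flow tables and a seeded synthetic-data generator emulating
    census-style zone tables, per-increment flooded-population exposure and
    county-to-county flow tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
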