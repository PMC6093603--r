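Package: marshplan
Title: Cost-Benefit Ranking of Tidal Marsh Adaptation Strategies Under
    Sea-Level Rise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A decision-support engine for coastal marsh conservation
    planning under uncertain sea-level rise.  Couples a simplified
    elevation-band marsh-fate simulator (with accretion feedback, marsh
    collapse, shoreline armoring, thin-layer sediment deposition and
    marsh-edge restoration) to a Monte-Carlo uncertainty analysis driven
    by Latin-Hypercube parameter sampling and spatially autocorrelated
    elevation-error fields.  Land-cover projections are summarised into
    landscape metrics, converted to stakeholder-weighted ecosystem-service
    utilities, combined with per-strategy cost models, and ranked by
    expected benefit per million dollars spent.  Includes a synthetic
    estuary generator, ESRI ASCII grid I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lhs,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
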