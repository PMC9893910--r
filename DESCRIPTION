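Package: basinfef
Title: Basin-Scale Water Footprint, Damage Accounting and the Food
    Environmental Footprint
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts land-use level outputs of a calibrated watershed
    nutrient model (annual pollutant loads, evapotranspiration with and
    without irrigation, crop yields and caloric values) into green, blue
    and grey water footprints, characterizes loads and water consumption
    into eutrophication and water-use midpoints, converts midpoints into
    human-health (DALY) and ecosystem (species.yr) endpoint damages with
    global normalization, aggregates normalized endpoints into a single
    cumulative impact using fixed (EPI) or entropy-derived weights, and
    computes the food environmental footprint (FEF): cumulative impact
    per unit of normalized nutrition production. Includes a scenario
    comparator for farm best-management practices (fertilizer and
    irrigation reduction, vegetated filter strips), a seeded synthetic
    basin generator for end-to-end testing without a watershed model
    run, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
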