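Package: lakecarb
Title: One-Dimensional Lake Inorganic Carbon Cycle with Calcite Precipitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale one-dimensional (depth-time) simulator of the inorganic
    carbon cycle of a hardwater lake. Couples a freshwater carbonate-system
    speciation solver (temperature-dependent equilibrium constants, Davies
    activity corrections, pH solution from DIC and alkalinity) to a
    threshold-triggered calcite precipitation module with exact reaction
    stoichiometry, particulate settling and sediment redissolution, diffusive
    air-water CO2 exchange, prescribed vertical mixing, river boundary
    exchange and prescribed net ecosystem production. Includes a seeded
    synthetic forcing generator emulating a warm-monomictic, moderately
    alkaline lake, paired enabled/muted precipitation experiments, day-of-year
    climatologies, seasonal carbon-flux budgets, and alkalinity-scaling
    regressions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
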