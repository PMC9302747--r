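Package: mangroveCarbon
Title: Mangrove Forest Inventory, Species Dominance Mapping and Aboveground
    Carbon Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for island-scale mangrove aboveground carbon assessment
    from plot inventories: species-indexed allometric biomass with
    mortality-status deductions, planar-intercept downed-wood carbon,
    community structure statistics (density, basal area, importance value),
    k-nearest-neighbour and random-forest dominant-species mapping over
    predictor grids, and strata-based upscaling of carbon stocks and
    area change between two extent maps. Includes a synthetic-data
    generator emulating a circular-plot survey so the full pipeline is
    testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    class,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
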