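Package: netmigr
Title: Gridded Net Human Migration from Subnational Vital Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates annual gridded net human migration from subnational
    birth and death statistics. Harmonizes raw subnational vital-rate series
    (combining small units, back-casting administrative splits, neighbour-based
    gap filling, national fallback, interpolation/extrapolation with
    macroregional trends, and national bias correction), downscales the
    harmonized rates to a grid with income-group linear regressions plus
    area-to-point kriging of areal residuals under a mass-preserving
    adjustment, derives net migration as reported population change minus
    natural change, delineates annual urban extents from relative population
    density and national urban shares, stratifies results into 100
    population-weighted socioclimatic bins (HDI by aridity deciles), and
    classifies the demographic impact and rural/urban direction of migration.
    Includes a synthetic-world generator with exact population bookkeeping so
    every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
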