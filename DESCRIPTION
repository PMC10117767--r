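Package: cmnutricycle
Title: Nutrient-Cycling and Nutrient-Management Economics for Cultured Meat
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A techno-economic nutrient-cycling model for cultured meat
    production compared with swine, beef, and broiler systems. Computes
    growth and feed-use metrics (specific growth rate, feed conversion
    ratio, protein conversion efficiency), areal protein and energy
    productivities of cropland with price-based co-product allocation,
    per-batch and annual spent-media nitrogen and chemical-oxygen-demand
    mass balances, land-application geometry and cost, wastewater-treatment
    cost, nitrogen-use-efficiency partitions with recovery targets, and
    seeded Monte-Carlo sensitivity ensembles over published parameter
    ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
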