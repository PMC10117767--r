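# cmnutricycle

A techno-economic nutrient-cycling model that compares cultured
(cell-cultivated) meat production with conventional swine, beef, and
broiler systems. Starting from a handful of physical parameters — cell
densities, bioreactor volume, conversion efficiencies, crop yields,
manure nitrogen availabilities, and unit costs — the package computes:

* **Growth and feed use**: specific growth rate, average daily gain,
  feed conversion ratio, and protein conversion efficiency (PCE) for
  each production system, treating one bioreactor batch as the
  cultured-meat "animal".
* **Areal productivity**: cropland per kg of meat through the soybean
  meal (protein) and corn starch (energy) supply chains with price-based
  co-product land allocation, expressed as g protein and MJ per m² per
  year.
* **Spent-media mass balance**: per-batch fed/retained/waste protein and
  nitrogen (0.16 kg N per kg protein), respired glucose from an
  oxygen-uptake model (332.2 nmol O₂/h per 10⁶ cells, 180:192
  glucose:O₂ stoichiometry), waste-glucose chemical oxygen demand
  (COD), and the spent-media N concentration.
* **Annual scenarios and costs**: a $10M/yr facility at $25/kg or
  $10/kg meat, in whole 345-kg batches; land-application geometry
  (168 kg N/ha onto the 35% corn fraction, hauling surcharge beyond a
  1-mile radius) and wastewater-treatment cost ($2.45/kg N +
  $0.40/kg COD), compared with conventional manure application.
* **Nitrogen-use efficiency**: retained/recoverable/lost partitions of
  fed N per system, the spent-media recovery rate needed for parity
  with each conventional system, and person-equivalents of the N load
  (13 g N/person/day).
* **Sensitivity**: seeded, bit-reproducible Monte-Carlo ensembles over
  declared parameter ranges and one-at-a-time tornado sweeps.

The model equations, parameter provenance, and known discrepancies with
the published figures it reproduces are documented in the methods
vignette, `vignettes/nutrient-cycling-model.Rmd`.

## Worked example

The packaged presets reproduce the published comparison out of the box.
The per-batch spent-media balance (15 m³ reactor, 345 kg harvest,
PCE 0.24):

```r
library(cmnutricycle)
round(unlist(batch_balance(preset_cm_batch())), 2)
#>       protein_retained            protein_fed          protein_waste
#>                  62.10                 258.75                 196.65
#>         nitrogen_waste            glucose_fed       glucose_respired
#>                  31.46                 710.29                  80.10
#>          oxygen_uptake       glucose_retained          glucose_waste
#>                  85.44                 120.75                 509.45
#>              cod_waste      wastewater_volume nitrogen_concentration
#>                 542.05                  29.71                   1.06
```

Each batch feeds ~259 kg protein and ~710 kg glucose, retains 62 kg of
protein in 345 kg of meat, respires 80 kg of glucose (11.3% of fed),
and discharges ~31.5 kg N and ~542 kg COD in ~30 m³ of spent media
(1.06 kg N/m³). Scaling to a $10M/yr facility:

```r
st <- scenario_table()
st[, c("meat_price", "annual_mass", "batches_per_year",
       "annual_nitrogen", "annual_cod")]
#>   meat_price annual_mass batches_per_year annual_nitrogen annual_cod
#> 1         25       4e+05             1160        36498.24   628780.3
#> 2         10       1e+06             2899        91214.14  1571408.8

round(st[, c("application_cost", "wwt_cost",
             "specific_application_cost", "specific_wwt_cost")], 2)
#>   application_cost wwt_cost specific_application_cost specific_wwt_cost
#> 1         113818.0 340932.8                      0.28              0.85
#> 2         322316.6 852038.1                      0.32              0.85
```

Nitrogen-use-efficiency partitions and the spent-media recovery needed
to match conventional systems:

```r
nue_table()$partitions
#>          system   retained recoverable      lost
#> 1         swine 0.16774194    0.362258 0.4700001
#> 2          beef 0.05238095    0.107619 0.8400000
#> 3       broiler 0.24210526    0.207895 0.5499997
#> 4 cultured meat 0.24000000    0.000000 0.7600000
```

Without nutrient recovery, cultured meat loses 76% of fed N — less than
beef (84%) but more than swine (47%) or broilers (55%).

Custom scenarios are YAML documents merged over the presets:

```r
b <- build_report("cm_batch:\n  protein_conversion_efficiency: 0.33\n")
write_tables(b, "report_out", format = "csv")
```

A command-line front end wrapping the same pipeline is installed at
`inst/cli/cmnutricycle.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cmnutricycle.R", package="cmnutricycle"))')" scenarios
```

## Package layout

| Area | Files |
| --- | --- |
| Parameter objects and presets | `R/specs.R`, `R/presets.R`, `R/units.R` |
| Growth and areal productivity | `R/growth.R`, `R/areal.R` |
| Nitrogen/COD balance and scaling | `R/nbalance.R` |
| Costs and nitrogen-use efficiency | `R/costs.R`, `R/nue.R` |
| Sensitivity sampler | `R/sampler.R` |
| Reporting and CLI | `R/report.R`, `inst/cli/cmnutricycle.R` |
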