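---
title: "Methods: the cultured-meat nutrient-cycling model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cultured-meat nutrient-cycling model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmnutricycle)
```

`cmnutricycle` implements a techno-economic nutrient-cycling model that
compares cultured (cell-cultivated) meat production with conventional
swine, beef, and broiler systems. It reproduces a published comparison
study's pipeline end to end: growth and feed-conversion metrics, areal
protein and energy productivity, the per-batch spent-media nitrogen and
glucose balance, annual production scenarios with land-application and
wastewater-treatment costs, nitrogen-use-efficiency partitions, and a
seeded Monte-Carlo sensitivity layer. This vignette documents the model
equations, the packaged parameter defaults and their provenance, the
design of the scenario generator, the deliberate numerical choices, and
the limitations - including published figures that the stated procedures
do not reproduce.

## 1. Model structure

### 1.1 Growth and protein conversion

For a conventional animal grown from birth weight $m_i$ to live weight
$m_f$ in $t$ days, the specific growth rate is
$\mu = \ln(m_f/m_i)/t$ and the average daily gain is $(m_f-m_i)/t$.
Total feed is live weight times the feed conversion ratio; protein fed
is feed times the diet protein fraction; protein output is edible mass
times the meat protein fraction. The protein conversion efficiency
(PCE) is protein output over protein fed.

The cultured-meat "animal" is one bioreactor batch: the birth weight is
the inoculum mass (initial cell density x reactor volume x wet mass per
cell), the live weight is the harvest mass, and the growth time is the
proliferation plus maturation duration. Its glucose feed per kg meat is
the meat energy density divided by the calorie conversion efficiency
and the glucose energy density; its protein feed per kg is the meat
protein fraction divided by the PCE.

```{r growth}
growth_table()
```

### 1.2 Areal productivity

Land per kg of crop is $10^4/(\text{yield} \times 10^3)$ m^2^ for yield
in t/ha. The cultured-meat protein chain runs through soybean meal and
the energy chain through corn starch; land is allocated to co-products
by price share, $s_i = m_i p_i / \sum_j m_j p_j$
(`price_allocation()`). Areal protein productivity is
$1000 f_{\text{protein}} / L$ g protein m^-2^ yr^-1^ and energy
productivity is $E \times 4.184 / 1000 / L$ MJ m^-2^ yr^-1^ for land
use $L$ in m^2^ yr per kg.

### 1.3 Per-batch spent-media balance

Waste protein is fed protein minus retained protein; waste nitrogen is
0.16 kg N per kg protein. The discharge water is the batch water minus
the water retained in the meat (83% moisture in the water balance),
giving the spent-media N concentration. Respired glucose follows an
oxygen-uptake model: 332.2 nmol O~2~ h^-1^ per 10^6^ cells, with the
proliferation-phase cell count taken as the arithmetic mean of the
initial and final counts and the maturation phase at the final count;
glucose converts from O~2~ at the 180:192 aerobic stoichiometry. Waste
glucose is fed minus retained minus respired, and its chemical oxygen
demand (COD) is waste glucose x 0.40 kg C/kg x 2.66 kg COD per kg C.

```{r batch}
batch_balance(preset_cm_batch())
```

### 1.4 Annual scenarios, costs, and nitrogen-use efficiency

A $10M/yr facility produces `revenue_target / price` kg/yr in whole
345-kg batches (`ceiling`); each reactor runs `floor(365/11)` = 33
batches/yr. Land application spreads N at 168 kg N/ha on the 35% of
surrounding land in corn; the service circle's fraction beyond 1 mile
is $(A - \pi r_t^2)/A$, and hauling beyond the threshold costs
$0.0035/gal instead of $0.0125/gal. Wastewater treatment costs
$2.45/kg N plus $0.40/kg COD. Nitrogen partitions are retained = PCE,
recoverable = available fraction x 0.98 capture x (0.80 for manure
spread on cropland; 0 for spent media without treatment), lost =
remainder; `recovery_to_match()` inverts this to find the spent-media
recovery needed for parity with a conventional system, and
`person_equivalents()` expresses the N load at 13 g N/person/day.

```{r scenarios}
scenario_table()[, c("meat_price", "annual_mass", "annual_nitrogen",
                     "annual_cod", "application_cost", "wwt_cost")]
```

## 2. Packaged defaults and provenance

All defaults live in `preset_animal()`, `preset_cm_batch()`,
`preset_feedstock()`, and `preset_econ_costs()`; `load_scenario()`
merges a YAML document over them, rejecting unknown keys by name.
Notable derived defaults:

* **Manure available-N fractions** are back-solved from the published
  lost-N fractions (beef 84%, swine 47%, broiler 55%) and the PCEs the
  presets themselves produce, via
  `available = (1 - lost - PCE)/(0.98 x 0.80)`, because the underlying
  manure-standard tables are not reproduced here. Override them with
  measured values where available.
* **Feedstock allocation shares** default to the published rounded
  price shares (soy meal 0.61, corn starch 0.74; `chain_mode =
  "as_printed"`). The exact price-based soy meal share is 0.602;
  `chain_mode = "stated_chain"` instead applies the full stated chain
  (meal fraction x protein content x recovery).
* **The batch spec carries two moisture fractions**: 0.70 for meat
  composition and 0.83 for the water balance, as published; the
  constructor keeps both explicit rather than reconciling them.
* **Harvest mass**: the published 345 kg/batch is inconsistent with the
  density-based mass (4x10^6^ cells/ml x 15 m^3^ x 3.5 ng = 210 kg).
  `cm_batch_spec()` warns when the stated mass departs >5% from the
  density-consistent one; the preset keeps the published 345 kg and
  suppresses that (documented) warning.

## 3. Scenario generator design

`sample_scenarios(n, seed, ranges, base)` draws independent parameters
from declared `parameter_range()` objects - uniform, log-uniform (for
the cell densities, which span an order of magnitude or more), or
triangular - using only `set.seed()` + `runif()` so ensembles are
bit-reproducible across platforms. Draws violating the joint
constraint `final_density >= initial_density` are rejected and redrawn
(capped, then an error). Each draw is rebuilt into a *consistent*
`cm_batch_spec`: harvest mass is recomputed from density x volume x
cell mass, and batch water is rescaled at the baseline water intensity,
so sampled scenarios never inherit the published mass inconsistency.
`run_ensemble()` evaluates nine registered metrics per draw, records
per-draw failures in an `error` column rather than aborting, and
summarises quantiles; `tornado()` does one-at-a-time endpoint sweeps
ranked by absolute swing.

```{r sampler}
ens <- sample_scenarios(200, seed = 7)
res <- run_ensemble(ens)
signif(res$summary, 3)
```

## 4. Numerical choices

* **Whole batches**: annual batch counts use `ceiling(mass/345)`
  (2,899 and 1,160), and reactors use `ceiling(batches/33)`. The
  published reactor count (35 for the high scenario) requires plain
  rounding of 35.2; we keep `ceiling` (36) for physical consistency.
* **Arithmetic-mean proliferation cell count** in the oxygen-uptake
  integral, per the stated procedure. A geometric mean option exists
  for comparison and gives lower uptake.
* **Ledger closure** is exact by construction (waste = fed - retained
  - respired); tests assert closure at 1e-14 relative tolerance over
  randomized specs.
* **Beyond-threshold fraction** uses the closed form
  $(A-\pi r_t^2)/A$; tests verify it against a 10^4^-cell radial
  midpoint quadrature.
* Full-precision values are carried everywhere; rounding happens only
  at presentation (e.g. the acceptance script reports annual COD at
  three significant figures and the respired-glucose share at one
  decimal).

## 5. Known irreproducibles and limitations

The test suite asserts published values at their printed precision
*except* where the stated procedure provably gives something else;
those cells are asserted at the computed value and documented:

* The published per-batch **oxygen uptake of 72 kg** is mutually
  inconsistent with the 80 kg of respired glucose it is said to yield;
  the stated procedure gives 85.4 kg O~2~, which reproduces the 80 kg
  of glucose (and the 11.3% respired share) exactly.
* The published **corn energy land (2.28 m^2^ yr/kg) and 4.58 total**
  cannot be derived from the stated corn chain; the computed footprint
  (1.75; total 4.06) lies between the allocated and unallocated chains.
* **Broiler feed** computes to 5.32 kg (printed 5.40), protein fed to
  0.904 kg (printed 0.92), and PCE to 24.2% (printed 25%); **beef PCE**
  computes to 5.24% (printed 5.0%).
* The **low-scenario application cost** computes to $322,317 (printed
  ~$332,000); treatment costs agree at two significant figures.

Structural limitations: parameters are sampled independently (no
correlation structure); the cost model is linear in N and COD loads
with a single distance threshold; the N partition treats "recoverable"
as a fixed capture x application chain rather than a process model; and
all prices and yields are single-region (US Midwest) snapshots.
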