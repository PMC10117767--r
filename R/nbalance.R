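#' Per-batch protein and nitrogen balance
#'
#' Protein retained in the meat is `batch mass x meat protein fraction`;
#' protein fed is retained / PCE; the difference ends up in the spent
#' media, carrying 16% of its mass as nitrogen.
#'
#' @param spec a [cm_batch_spec()].
#' @return list: `protein_retained`, `protein_fed`, `protein_waste`,
#'   `nitrogen_waste` (kg per batch).
#' @export
batch_protein_nitrogen <- function(spec) {
  stopifnot(inherits(spec, "cm_batch_spec"))
  k <- cm_constants()
  retained <- spec$batch_meat_mass * spec$meat_protein_fraction
  fed <- retained / spec$protein_conversion_efficiency
  waste <- fed - retained
  list(
    protein_retained = retained,
    protein_fed = fed,
    protein_waste = waste,
    nitrogen_waste = k$protein_n_fraction * waste
  )
}

#' Per-batch wastewater volume
#'
#' Water not leaving in the meat: `water per batch - meat mass x moisture
#' / 1,000` m3. The moisture used here is the water-balance moisture (83%
#' by default), kept separate from the product's nominal moisture content.
#'
#' @param spec a [cm_batch_spec()].
#' @param include_cleaning if `TRUE`, cleaning water joins the spent-media
#'   stream (what-if option; default `FALSE`, handled separately).
#' @return m3 per batch.
#' @export
batch_water <- function(spec, include_cleaning = FALSE) {
  stopifnot(inherits(spec, "cm_batch_spec"))
  meat_water <- spec$batch_meat_mass * spec$water_balance_moisture / 1000
  ww <- spec$water_per_batch - meat_water
  if (include_cleaning) ww <- ww + spec$cleaning_water_per_batch
  if (ww < 0) stop("negative wastewater volume", call. = FALSE)
  ww
}

#' Spent-media nitrogen concentration
#'
#' @param nitrogen kg N.
#' @param volume m3, > 0.
#' @return kg N per m3. Scale-invariant: identical for one batch or a
#'   year of batches with fixed batch parameters.
#' @export
nitrogen_concentration <- function(nitrogen, volume) {
  if (any(volume <= 0)) stop("volume must be > 0", call. = FALSE)
  nitrogen / volume
}

#' Per-batch oxygen uptake
#'
#' Respiration over the batch: the oxygen uptake rate (nmol O2 h^-1 per
#' 1e6 cells) applied to a representative proliferation-phase cell count
#' times the proliferation duration, plus the final cell count times the
#' maturation duration. The representative proliferation count is the
#' arithmetic mean of initial and final total counts by default; a
#' geometric-mean alternative is available.
#'
#' @param spec a [cm_batch_spec()].
#' @param proliferation_mean `"arithmetic"` (default) or `"geometric"`.
#' @return kg O2 per batch.
#' @export
oxygen_uptake <- function(spec,
                          proliferation_mean = c("arithmetic",
                                                 "geometric")) {
  stopifnot(inherits(spec, "cm_batch_spec"))
  proliferation_mean <- match.arg(proliferation_mean)
  k <- cm_constants()
  ml <- spec$reactor_volume * 1e6
  n0 <- spec$initial_cell_density * ml
  nf <- spec$final_cell_density * ml
  n_prolif <- switch(proliferation_mean,
                     arithmetic = (n0 + nf) / 2,
                     geometric = sqrt(n0 * nf))
  cell_hours <- n_prolif * spec$proliferation_duration +
    nf * spec$maturation_duration
  # rate is per 1e6 cells; nmol -> mol -> kg
  mol <- spec$oxygen_uptake_rate * 1e-9 * cell_hours / 1e6
  mol * k$o2_g_per_mol / 1000
}

#' Glucose respired for a given oxygen uptake
#'
#' Complete aerobic oxidation: 180 g glucose consumes 192 g O2.
#'
#' @param oxygen kg O2, >= 0.
#' @return kg glucose.
#' @export
glucose_respired <- function(oxygen) {
  if (any(oxygen < 0)) stop("oxygen must be >= 0", call. = FALSE)
  oxygen * cm_constants()$glucose_per_o2
}

#' Glucose waste and chemical oxygen demand
#'
#' Closes the glucose ledger: retained glucose is the calorie conversion
#' efficiency times the feed, respired glucose comes from the oxygen
#' uptake, and the remainder is waste. Waste glucose is 40% carbon, and
#' each kg of that carbon exerts 2.66 kg COD.
#'
#' @param spec a [cm_batch_spec()].
#' @param glucose_fed kg glucose per batch.
#' @param respired kg glucose respired per batch.
#' @return list: `glucose_retained`, `glucose_waste`, `cod_waste` (kg).
#' @export
glucose_cod <- function(spec, glucose_fed, respired) {
  stopifnot(inherits(spec, "cm_batch_spec"))
  k <- cm_constants()
  retained <- spec$calorie_conversion_efficiency * glucose_fed
  waste <- glucose_fed - retained - respired
  if (waste < 0) stop("negative glucose waste: fed < retained + respired",
                      call. = FALSE)
  list(
    glucose_retained = retained,
    glucose_waste = waste,
    cod_waste = waste * k$glucose_carbon_fraction * k$cod_per_kg_carbon
  )
}

#' Complete per-batch mass balance
#'
#' Runs the protein/nitrogen, water, oxygen, and glucose/COD balances for
#' one batch and assembles them into a single ledger. Both the protein
#' ledger (`fed = retained + waste`) and the glucose ledger
#' (`fed = retained + respired + waste`) close exactly by construction.
#'
#' @param spec a [cm_batch_spec()].
#' @param proliferation_mean passed to [oxygen_uptake()].
#' @param include_cleaning passed to [batch_water()].
#' @return An object of class `batch_balance`: all protein, glucose,
#'   oxygen, COD, water and concentration terms, in kg and m3 per batch.
#' @export
batch_balance <- function(spec, proliferation_mean = "arithmetic",
                          include_cleaning = FALSE) {
  stopifnot(inherits(spec, "cm_batch_spec"))
  pn <- batch_protein_nitrogen(spec)
  glucose_fed <- glucose_feed_per_kg(
    spec$meat_energy_density, spec$calorie_conversion_efficiency,
    spec$glucose_energy_density) * spec$batch_meat_mass
  o2 <- oxygen_uptake(spec, proliferation_mean)
  resp <- glucose_respired(o2)
  gc <- glucose_cod(spec, glucose_fed, resp)
  ww <- batch_water(spec, include_cleaning)
  structure(
    c(pn,
      list(
        glucose_fed = glucose_fed,
        glucose_respired = resp,
        oxygen_uptake = o2
      ),
      gc,
      list(
        wastewater_volume = ww,
        nitrogen_concentration = nitrogen_concentration(pn$nitrogen_waste,
                                                        ww)
      )),
    class = "batch_balance"
  )
}

#' Scale a batch balance to an annual production scenario
#'
#' A facility targeting a given annual revenue at a given meat price must
#' produce `revenue / price` kg per year, i.e. `ceiling(mass / batch
#' mass)` batches. Reactors cycle at most `floor(365 / batch days)`
#' batches per year. Annual waste loads are the exact per-batch loads
#' times the batch count.
#'
#' @param spec a [cm_batch_spec()].
#' @param price $ per kg meat, > 0.
#' @param revenue_target $ per year.
#' @param batch a [batch_balance()]; computed from `spec` when omitted.
#' @return An object of class `production_scenario`: `meat_price`,
#'   `revenue_target`, `annual_mass`, `batches_per_year`, `batch_days`,
#'   `batches_per_reactor_year`, `reactors`, `annual_nitrogen`,
#'   `annual_cod`, `annual_wastewater`, and the underlying `batch` ledger.
#' @export
scale_scenario <- function(spec, price, revenue_target = 1e7,
                           batch = batch_balance(spec)) {
  stopifnot(inherits(spec, "cm_batch_spec"))
  if (price <= 0) stop("price must be > 0", call. = FALSE)
  k <- cm_constants()
  annual_mass <- revenue_target / price
  batches <- ceiling(annual_mass / spec$batch_meat_mass)
  per_reactor <- floor(k$days_per_year / spec$batch_days)
  structure(
    list(
      meat_price = price,
      revenue_target = revenue_target,
      annual_mass = annual_mass,
      batches_per_year = batches,
      batch_days = spec$batch_days,
      batches_per_reactor_year = per_reactor,
      reactors = if (batches > 0) ceiling(batches / per_reactor) else 0,
      annual_nitrogen = batch$nitrogen_waste * batches,
      annual_cod = batch$cod_waste * batches,
      annual_wastewater = batch$wastewater_volume * batches,
      batch = batch
    ),
    class = "production_scenario"
  )
}
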