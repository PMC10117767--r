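#' @importFrom stats quantile setNames
#' @importFrom utils modifyList write.csv
NULL

.check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("field '%s' must be a number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  }
  x
}

.check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("field '%s' must be %s", name,
                 if (strict) "> 0" else ">= 0"), call. = FALSE)
  }
  x
}

#' Conventional-animal production parameters
#'
#' Bundles the growth, feed, carcass, and manure parameters of one
#' conventional meat species (swine, beef, or broiler) used throughout the
#' model: endpoint weights, edible fraction, meat composition, growth time,
#' feed conversion ratio, diet protein content, lifetime manure volume, and
#' the fraction of fed nitrogen recoverable from land-applied manure after
#' volatilization and leaching.
#'
#' @param species character label.
#' @param birth_weight,live_weight kg; `live_weight > birth_weight > 0`.
#' @param edible_fraction edible meat as a fraction of live weight, in
#'   \[0, 1\].
#' @param meat_protein_fraction kg protein per kg wet meat.
#' @param meat_moisture_fraction fraction of wet meat that is water.
#' @param growth_time days from birth to slaughter (gestation excluded).
#' @param feed_conversion_ratio kg feed per kg live weight.
#' @param diet_protein_fraction protein fraction of the feed.
#' @param lifetime_manure_volume litres of manure per animal lifetime.
#' @param manure_available_n_fraction fraction of fed N present as
#'   plant-available N in the manure before volatilization/leaching
#'   corrections (see [animal_partition()]).
#' @return An object of class `animal_spec`.
#' @export
animal_spec <- function(species,
                        birth_weight,
                        live_weight,
                        edible_fraction,
                        meat_protein_fraction,
                        meat_moisture_fraction,
                        growth_time,
                        feed_conversion_ratio,
                        diet_protein_fraction,
                        lifetime_manure_volume = 0,
                        manure_available_n_fraction = 0) {
  .check_positive(birth_weight, "birth_weight")
  .check_positive(live_weight, "live_weight")
  if (live_weight <= birth_weight) {
    stop("live_weight must exceed birth_weight", call. = FALSE)
  }
  .check_fraction(edible_fraction, "edible_fraction")
  .check_fraction(meat_protein_fraction, "meat_protein_fraction")
  .check_fraction(meat_moisture_fraction, "meat_moisture_fraction")
  .check_positive(growth_time, "growth_time")
  .check_positive(feed_conversion_ratio, "feed_conversion_ratio")
  .check_fraction(diet_protein_fraction, "diet_protein_fraction")
  .check_positive(lifetime_manure_volume, "lifetime_manure_volume",
                  strict = FALSE)
  .check_fraction(manure_available_n_fraction, "manure_available_n_fraction")
  structure(
    list(
      species = species,
      birth_weight = birth_weight,
      live_weight = live_weight,
      edible_fraction = edible_fraction,
      meat_protein_fraction = meat_protein_fraction,
      meat_moisture_fraction = meat_moisture_fraction,
      growth_time = growth_time,
      feed_conversion_ratio = feed_conversion_ratio,
      diet_protein_fraction = diet_protein_fraction,
      lifetime_manure_volume = lifetime_manure_volume,
      manure_available_n_fraction = manure_available_n_fraction
    ),
    class = "animal_spec"
  )
}

#' Cultured-meat bioreactor batch parameters
#'
#' Describes one production batch in the final bioreactor: cell densities
#' over the proliferation phase, per-cell wet mass, phase durations, the
#' harvested meat mass and its composition, water use, oxygen uptake rate,
#' and the protein and calorie conversion efficiencies that drive every
#' downstream feed and waste computation.
#'
#' The harvested `batch_meat_mass` is accepted as given even when it
#' disagrees with `final_cell_density * cell_wet_mass * reactor_volume`
#' (the constructor warns but does not error); the published source model
#' carries the same internal inconsistency.
#'
#' @param reactor_volume m3 working volume.
#' @param initial_cell_density,final_cell_density cells per ml at start and
#'   end of the proliferation phase; `final >= initial`.
#' @param cell_wet_mass grams wet mass per cell.
#' @param proliferation_duration,maturation_duration hours.
#' @param batch_meat_mass kg wet meat harvested per batch.
#' @param meat_protein_fraction kg protein per kg wet meat (default 0.18).
#' @param meat_moisture_fraction moisture fraction of the meat product
#'   (default 0.70); see `water_balance_moisture` for the water ledger.
#' @param water_balance_moisture moisture fraction used in the water mass
#'   balance (default 0.83); kept distinct from `meat_moisture_fraction`
#'   because the two published figures differ and are used in different
#'   computations.
#' @param water_per_batch m3 media water per batch (cleaning water excluded).
#' @param cleaning_water_per_batch m3 cleaning water per batch, handled as a
#'   separate stream by default.
#' @param oxygen_uptake_rate nmol O2 per hour per 1e6 cells.
#' @param meat_energy_density kcal per kg wet meat.
#' @param protein_conversion_efficiency fraction of fed protein retained in
#'   the meat, in (0, 1].
#' @param calorie_conversion_efficiency fraction of fed glucose energy
#'   retained, in (0, 1].
#' @param glucose_energy_density kcal per kg glucose.
#' @param batch_days calendar days per batch including turnaround, used for
#'   reactor scheduling.
#' @return An object of class `cm_batch_spec`.
#' @export
cm_batch_spec <- function(reactor_volume,
                          initial_cell_density,
                          final_cell_density,
                          cell_wet_mass,
                          proliferation_duration,
                          maturation_duration,
                          batch_meat_mass,
                          meat_protein_fraction = 0.18,
                          meat_moisture_fraction = 0.70,
                          water_balance_moisture = 0.83,
                          water_per_batch,
                          cleaning_water_per_batch = 0,
                          oxygen_uptake_rate,
                          meat_energy_density = 1400,
                          protein_conversion_efficiency = 0.24,
                          calorie_conversion_efficiency = 0.17,
                          glucose_energy_density = 4000,
                          batch_days = 11) {
  .check_positive(reactor_volume, "reactor_volume", strict = FALSE)
  .check_positive(initial_cell_density, "initial_cell_density")
  .check_positive(final_cell_density, "final_cell_density")
  if (final_cell_density < initial_cell_density) {
    stop("final_cell_density must be >= initial_cell_density", call. = FALSE)
  }
  .check_positive(cell_wet_mass, "cell_wet_mass")
  .check_positive(proliferation_duration, "proliferation_duration",
                  strict = FALSE)
  .check_positive(maturation_duration, "maturation_duration", strict = FALSE)
  .check_positive(batch_meat_mass, "batch_meat_mass")
  .check_fraction(meat_protein_fraction, "meat_protein_fraction")
  .check_fraction(meat_moisture_fraction, "meat_moisture_fraction")
  .check_fraction(water_balance_moisture, "water_balance_moisture")
  .check_positive(water_per_batch, "water_per_batch")
  .check_positive(cleaning_water_per_batch, "cleaning_water_per_batch",
                  strict = FALSE)
  .check_positive(oxygen_uptake_rate, "oxygen_uptake_rate", strict = FALSE)
  .check_positive(meat_energy_density, "meat_energy_density")
  .check_fraction(protein_conversion_efficiency,
                  "protein_conversion_efficiency", lo = 1e-12)
  .check_fraction(calorie_conversion_efficiency,
                  "calorie_conversion_efficiency", lo = 1e-12)
  .check_positive(glucose_energy_density, "glucose_energy_density")
  .check_positive(batch_days, "batch_days")
  if (water_per_batch <= batch_meat_mass * water_balance_moisture / 1000) {
    stop("water_per_batch must exceed the water content of the meat",
         call. = FALSE)
  }
  harvest_mass <- final_cell_density * reactor_volume * 1e6 *
    cell_wet_mass / 1000
  if (reactor_volume > 0 &&
      abs(harvest_mass - batch_meat_mass) > 0.05 * batch_meat_mass) {
    warning(sprintf(
      paste0("batch_meat_mass (%.0f kg) differs from final density x cell ",
             "mass x volume (%.0f kg); inherited from the source model"),
      batch_meat_mass, harvest_mass), call. = FALSE)
  }
  structure(
    list(
      reactor_volume = reactor_volume,
      initial_cell_density = initial_cell_density,
      final_cell_density = final_cell_density,
      cell_wet_mass = cell_wet_mass,
      proliferation_duration = proliferation_duration,
      maturation_duration = maturation_duration,
      batch_meat_mass = batch_meat_mass,
      meat_protein_fraction = meat_protein_fraction,
      meat_moisture_fraction = meat_moisture_fraction,
      water_balance_moisture = water_balance_moisture,
      water_per_batch = water_per_batch,
      cleaning_water_per_batch = cleaning_water_per_batch,
      oxygen_uptake_rate = oxygen_uptake_rate,
      meat_energy_density = meat_energy_density,
      protein_conversion_efficiency = protein_conversion_efficiency,
      calorie_conversion_efficiency = calorie_conversion_efficiency,
      glucose_energy_density = glucose_energy_density,
      batch_days = batch_days
    ),
    class = "cm_batch_spec"
  )
}

#' Crop-to-media-ingredient feedstock chain
#'
#' One crop supplying a media ingredient: agronomic yield, co-product mass
#' fractions and prices (for price-based land allocation), the nutrient
#' content of the usable component, and the recovery efficiency of the
#' processing chain.
#'
#' @param crop character label.
#' @param yield Mg per ha per year.
#' @param component_fractions named numeric vector of co-product mass
#'   fractions (e.g. `c(meal = 0.80, oil = 0.20)`); must sum to <= 1.
#' @param component_prices named numeric vector, $ per kg, same names.
#' @param usable_component name of the component feeding the media chain.
#' @param nutrient_fraction nutrient mass per kg of the usable component
#'   (e.g. 0.48 kg protein per kg soybean meal, 0.67 kg starch per kg corn).
#' @param recovery_fraction fraction of the component nutrient recovered in
#'   the final media ingredient (e.g. 0.80 for hydrolysate).
#' @param allocation_share land-use share assigned to the usable component.
#'   If `NA`, the exact price-based share from [price_allocation()] is used.
#' @param chain_mode `"as_printed"` or `"stated_chain"`; see
#'   [soy_land_per_kg_cm()].
#' @return An object of class `feedstock_chain`.
#' @export
feedstock_chain <- function(crop,
                            yield,
                            component_fractions,
                            component_prices,
                            usable_component,
                            nutrient_fraction,
                            recovery_fraction = 1,
                            allocation_share = NA_real_,
                            chain_mode = c("as_printed", "stated_chain")) {
  chain_mode <- match.arg(chain_mode)
  .check_positive(yield, "yield")
  if (is.null(names(component_fractions)) ||
      !setequal(names(component_fractions), names(component_prices))) {
    stop("component_fractions and component_prices must share names",
         call. = FALSE)
  }
  if (any(component_fractions < 0) || sum(component_fractions) > 1 + 1e-9) {
    stop("component mass fractions must be >= 0 and sum to <= 1",
         call. = FALSE)
  }
  if (any(component_prices < 0)) stop("prices must be >= 0", call. = FALSE)
  if (!usable_component %in% names(component_fractions)) {
    stop("usable_component not among components", call. = FALSE)
  }
  .check_fraction(nutrient_fraction, "nutrient_fraction")
  .check_fraction(recovery_fraction, "recovery_fraction")
  if (!is.na(allocation_share)) {
    .check_fraction(allocation_share, "allocation_share")
  }
  structure(
    list(
      crop = crop,
      yield = yield,
      component_fractions = component_fractions,
      component_prices = component_prices[names(component_fractions)],
      usable_component = usable_component,
      nutrient_fraction = nutrient_fraction,
      recovery_fraction = recovery_fraction,
      allocation_share = allocation_share,
      chain_mode = chain_mode
    ),
    class = "feedstock_chain"
  )
}

#' Economic unit costs for nutrient management
#'
#' @param application_base_cost $ per US gallon land-applied.
#' @param application_distance_surcharge $ per gallon for volume destined
#'   beyond `distance_threshold`.
#' @param distance_threshold miles; hauling beyond this radius incurs the
#'   surcharge.
#' @param n_treatment_cost $ per kg Total Kjeldahl Nitrogen treated.
#' @param cod_treatment_cost $ per kg COD treated.
#' @param n_application_rate kg N per ha per year agronomic rate.
#' @param corn_land_fraction fraction of surrounding land growing the
#'   receiving crop; dilutes the service area.
#' @param n_fertilizer_price_range $ per kg N, `c(low, high)`.
#' @return An object of class `econ_costs`.
#' @export
econ_costs <- function(application_base_cost = 0.0125,
                       application_distance_surcharge = 0.0035,
                       distance_threshold = 1,
                       n_treatment_cost = 2.45,
                       cod_treatment_cost = 0.40,
                       n_application_rate = 168,
                       corn_land_fraction = 0.35,
                       n_fertilizer_price_range = c(1, 3)) {
  for (f in c("application_base_cost", "application_distance_surcharge",
              "distance_threshold", "n_treatment_cost",
              "cod_treatment_cost")) {
    .check_positive(get(f), f, strict = FALSE)
  }
  .check_positive(n_application_rate, "n_application_rate")
  .check_fraction(corn_land_fraction, "corn_land_fraction", lo = 1e-12)
  if (any(n_fertilizer_price_range < 0) ||
      n_fertilizer_price_range[1] > n_fertilizer_price_range[2]) {
    stop("n_fertilizer_price_range must be an increasing pair >= 0",
         call. = FALSE)
  }
  structure(
    list(
      application_base_cost = application_base_cost,
      application_distance_surcharge = application_distance_surcharge,
      distance_threshold = distance_threshold,
      n_treatment_cost = n_treatment_cost,
      cod_treatment_cost = cod_treatment_cost,
      n_application_rate = n_application_rate,
      corn_land_fraction = corn_land_fraction,
      n_fertilizer_price_range = n_fertilizer_price_range
    ),
    class = "econ_costs"
  )
}

#' @export
print.animal_spec <- function(x, ...) {
  cat(sprintf("<animal_spec> %s: %g -> %g kg over %g d, FCR %g\n",
              x$species, x$birth_weight, x$live_weight, x$growth_time,
              x$feed_conversion_ratio))
  invisible(x)
}

#' @export
print.cm_batch_spec <- function(x, ...) {
  cat(sprintf(
    "<cm_batch_spec> %g m3 reactor, %g kg meat/batch, PCE %g, CCE %g\n",
    x$reactor_volume, x$batch_meat_mass,
    x$protein_conversion_efficiency, x$calorie_conversion_efficiency))
  invisible(x)
}
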