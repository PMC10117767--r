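#' Land-application area and service radius
#'
#' Area needed to land-apply an annual nitrogen load at the agronomic
#' rate, inflated for the fraction of surrounding land actually growing
#' the receiving crop, and the radius of the equivalent service circle
#' centred on the facility.
#'
#' @param annual_n kg N per year.
#' @param rate kg N per ha per year, > 0.
#' @param corn_fraction fraction of land growing the receiving crop,
#'   in (0, 1].
#' @return list: `required_area` (ha), `adjusted_area` (ha),
#'   `service_radius_km`.
#' @examples
#' application_area(36500, 168, 0.35)
#' @export
application_area <- function(annual_n, rate = 168, corn_fraction = 0.35) {
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (corn_fraction <= 0 || corn_fraction > 1) {
    stop("corn_fraction must be in (0, 1]", call. = FALSE)
  }
  area <- annual_n / rate
  adjusted <- area / corn_fraction
  radius_m <- sqrt(adjusted * cm_constants()$m2_per_ha / pi)
  list(
    required_area = area,
    adjusted_area = adjusted,
    service_radius_km = radius_m / 1000
  )
}

#' Fraction of the service area beyond a hauling threshold
#'
#' With the facility at the centre of a circular service area and the
#' waste applied uniformly, the volume hauled beyond a threshold radius
#' is proportional to the area of the annulus beyond it:
#' `max(0, (A - pi r_t^2) / A)`.
#'
#' @param adjusted_area ha.
#' @param threshold_miles threshold radius, miles.
#' @return fraction in \[0, 1\].
#' @export
fraction_beyond_threshold <- function(adjusted_area, threshold_miles = 1) {
  k <- cm_constants()
  if (adjusted_area <= 0) return(0)
  thresh_ha <- pi * (threshold_miles * k$m_per_mile)^2 / k$m2_per_ha
  max(0, (adjusted_area - thresh_ha) / adjusted_area)
}

#' Annual land-application cost for spent media
#'
#' Every gallon pays the base application cost; gallons destined beyond
#' the threshold radius pay a flat distance surcharge on top. The volume
#' split follows [fraction_beyond_threshold()] (uniform application).
#'
#' @param volume m3 per year.
#' @param adjusted_area ha (from [application_area()]).
#' @param econ an [econ_costs()].
#' @return list: `gallons`, `fraction_beyond`, `base_cost`,
#'   `surcharge_cost`, `total_cost` ($ per year).
#' @export
application_cost <- function(volume, adjusted_area,
                             econ = preset_econ_costs()) {
  stopifnot(inherits(econ, "econ_costs"), volume >= 0)
  k <- cm_constants()
  gallons <- volume * k$gallon_per_m3
  frac <- fraction_beyond_threshold(adjusted_area, econ$distance_threshold)
  base <- gallons * econ$application_base_cost
  sur <- gallons * frac * econ$application_distance_surcharge
  list(
    gallons = gallons,
    fraction_beyond = frac,
    base_cost = base,
    surcharge_cost = sur,
    total_cost = base + sur
  )
}

#' Annual wastewater-treatment cost
#'
#' Municipal treatment charges per kg of Total Kjeldahl Nitrogen and per
#' kg of COD, plus the specific (per kg meat) breakdown.
#'
#' @param annual_n kg N per year.
#' @param annual_cod kg COD per year.
#' @param econ an [econ_costs()].
#' @param annual_mass kg meat per year, > 0.
#' @return list: `n_cost`, `cod_cost`, `total_cost` ($/yr);
#'   `specific_n`, `specific_cod`, `specific_total` ($/kg meat).
#' @export
wwt_cost <- function(annual_n, annual_cod, econ = preset_econ_costs(),
                     annual_mass) {
  stopifnot(inherits(econ, "econ_costs"))
  if (annual_mass <= 0) stop("annual_mass must be > 0", call. = FALSE)
  n_cost <- annual_n * econ$n_treatment_cost
  cod_cost <- annual_cod * econ$cod_treatment_cost
  list(
    n_cost = n_cost,
    cod_cost = cod_cost,
    total_cost = n_cost + cod_cost,
    specific_n = n_cost / annual_mass,
    specific_cod = cod_cost / annual_mass,
    specific_total = (n_cost + cod_cost) / annual_mass
  )
}

#' Manure land-application cost per kg meat
#'
#' Lifetime manure volume per animal at the base application cost, spread
#' over the animal's edible meat output.
#'
#' @param animal an [animal_spec()].
#' @param econ an [econ_costs()].
#' @return $ per kg meat.
#' @export
manure_application_cost <- function(animal, econ = preset_econ_costs()) {
  stopifnot(inherits(animal, "animal_spec"), inherits(econ, "econ_costs"))
  meat <- animal$live_weight * animal$edible_fraction
  if (meat <= 0) stop("meat output must be > 0", call. = FALSE)
  gallons <- animal$lifetime_manure_volume / 1000 *
    cm_constants()$gallon_per_m3
  gallons * econ$application_base_cost / meat
}

#' Nutrient-management cost comparison table
#'
#' Per-kg costs of manure land application for each conventional species
#' alongside spent-media land application and wastewater treatment for
#' the cultured-meat production scenarios.
#'
#' @param scenario output of [load_scenario()].
#' @param prices $ per kg meat for the production scenarios (default the
#'   high/low pair 25 and 10).
#' @param revenue_target $ per year (default 1e7).
#' @return data frame: `system`, `strategy`, `annual_cost`,
#'   `specific_cost` ($ per kg meat).
#' @export
cost_table <- function(scenario = load_scenario(), prices = c(25, 10),
                       revenue_target = 1e7) {
  econ <- scenario$economics
  rows <- lapply(names(scenario$animals), function(sp) {
    data.frame(system = sp, strategy = "manure application",
               annual_cost = NA_real_,
               specific_cost = manure_application_cost(
                 scenario$animals[[sp]], econ),
               stringsAsFactors = FALSE)
  })
  bb <- batch_balance(scenario$cm_batch)
  for (p in prices) {
    sc <- scale_scenario(scenario$cm_batch, p, revenue_target, bb)
    geom <- application_area(sc$annual_nitrogen, econ$n_application_rate,
                             econ$corn_land_fraction)
    app <- application_cost(sc$annual_wastewater, geom$adjusted_area, econ)
    wwt <- wwt_cost(sc$annual_nitrogen, sc$annual_cod, econ,
                    sc$annual_mass)
    rows <- c(rows, list(
      data.frame(system = sprintf("cultured meat ($%g/kg)", p),
                 strategy = "spent-media application",
                 annual_cost = app$total_cost,
                 specific_cost = app$total_cost / sc$annual_mass,
                 stringsAsFactors = FALSE),
      data.frame(system = sprintf("cultured meat ($%g/kg)", p),
                 strategy = "wastewater treatment",
                 annual_cost = wwt$total_cost,
                 specific_cost = wwt$specific_total,
                 stringsAsFactors = FALSE)
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
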