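#' Physical constants and unit conversions
#'
#' A small fixed registry of the unit conversions and physico-chemical
#' constants the nutrient-cycling model needs. This is deliberately not a
#' general-purpose unit system: only the pairs used by the model are
#' registered, and the constants are immutable.
#'
#' @return A named list of constants:
#' \describe{
#'   \item{gallon_per_m3}{US gallons per cubic metre (264.172).}
#'   \item{m_per_mile}{metres per statute mile (1,609.34).}
#'   \item{m2_per_ha}{square metres per hectare (10,000).}
#'   \item{kj_per_kcal}{kilojoules per kilocalorie (4.184).}
#'   \item{protein_n_fraction}{kg N per kg protein (0.16).}
#'   \item{glucose_carbon_fraction}{kg C per kg glucose (0.40).}
#'   \item{cod_per_kg_carbon}{kg COD per kg carbon in glucose (2.66).}
#'   \item{glucose_per_o2}{kg glucose respired per kg O2 consumed under
#'     complete aerobic oxidation, 180/192.}
#'   \item{o2_g_per_mol}{grams O2 per mole (32).}
#'   \item{person_n_excretion_g_day}{human N excretion, g per person per
#'     day (13).}
#'   \item{days_per_year}{365.}
#' }
#' @export
cm_constants <- function() {
  list(
    gallon_per_m3 = 264.172,
    m_per_mile = 1609.34,
    m2_per_ha = 10000,
    kj_per_kcal = 4.184,
    protein_n_fraction = 0.16,
    glucose_carbon_fraction = 0.40,
    cod_per_kg_carbon = 2.66,
    glucose_per_o2 = 180 / 192,
    o2_g_per_mol = 32,
    person_n_excretion_g_day = 13,
    days_per_year = 365
  )
}

# conversion factors: value[to] = value[from] * factor["from->to"]
.unit_pairs <- function() {
  k <- cm_constants()
  c(
    "m3->gallon" = k$gallon_per_m3,
    "gallon->m3" = 1 / k$gallon_per_m3,
    "mile->m" = k$m_per_mile,
    "m->mile" = 1 / k$m_per_mile,
    "ha->m2" = k$m2_per_ha,
    "m2->ha" = 1 / k$m2_per_ha,
    "kcal->kJ" = k$kj_per_kcal,
    "kJ->kcal" = 1 / k$kj_per_kcal,
    "L->m3" = 1e-3,
    "m3->L" = 1e3,
    "kg_ha->kg_m2" = 1 / k$m2_per_ha,
    "kg_m2->kg_ha" = k$m2_per_ha
  )
}

#' Convert a quantity between registered units
#'
#' @param value numeric vector.
#' @param from,to unit names; the pair must be registered. Registered units:
#'   `m3`, `gallon`, `mile`, `m`, `ha`, `m2`, `kcal`, `kJ`, `L`,
#'   `kg_ha`, `kg_m2`.
#' @return `value` expressed in `to` units.
#' @examples
#' convert_unit(30, "m3", "gallon")   # 7925.16
#' convert_unit(168, "kg_ha", "kg_m2") # 0.0168
#' @export
convert_unit <- function(value, from, to) {
  stopifnot(is.numeric(value), length(from) == 1L, length(to) == 1L)
  if (identical(from, to)) return(value)
  key <- paste0(from, "->", to)
  pairs <- .unit_pairs()
  if (!key %in% names(pairs)) {
    stop("unregistered unit pair: ", from, " -> ", to, call. = FALSE)
  }
  value * unname(pairs[[key]])
}
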