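#' Protein feed requirement per kg cultured meat
#'
#' `meat protein fraction / protein conversion efficiency`: the mass of
#' feed protein (e.g. soybean hydrolysate protein) needed per kg of wet
#' meat after conversion losses.
#'
#' @param meat_protein_fraction kg protein per kg wet meat.
#' @param pce protein conversion efficiency, in (0, 1].
#' @return kg feed protein per kg meat.
#' @examples
#' protein_feed_per_kg(0.18, 0.24)  # 0.75
#' @export
protein_feed_per_kg <- function(meat_protein_fraction, pce) {
  if (any(pce <= 0) || any(pce > 1)) stop("pce must be in (0, 1]",
                                          call. = FALSE)
  meat_protein_fraction / pce
}

#' Glucose feed requirement per kg cultured meat
#'
#' `meat energy density / calorie conversion efficiency / glucose energy
#' density`.
#'
#' @param meat_energy kcal per kg meat.
#' @param calorie_efficiency fraction of fed glucose energy retained,
#'   in (0, 1].
#' @param glucose_energy kcal per kg glucose (default 4,000).
#' @return kg glucose per kg meat.
#' @examples
#' glucose_feed_per_kg(1400, 0.17)  # ~2.06 kg
#' @export
glucose_feed_per_kg <- function(meat_energy, calorie_efficiency,
                                glucose_energy = 4000) {
  if (any(calorie_efficiency <= 0) || any(calorie_efficiency > 1)) {
    stop("calorie_efficiency must be in (0, 1]", call. = FALSE)
  }
  if (any(glucose_energy <= 0)) stop("glucose_energy must be > 0",
                                     call. = FALSE)
  meat_energy / calorie_efficiency / glucose_energy
}

#' Cropland per kg of crop
#'
#' Reciprocal of agronomic yield: `10,000 m2 / (yield Mg/ha x 1,000)`.
#'
#' @param yield Mg per ha per year, > 0.
#' @return m2 per kg crop.
#' @examples
#' crop_land_per_kg(4.12)  # soy, ~2.43 m2/kg
#' crop_land_per_kg(13)    # corn, ~0.77 m2/kg
#' @export
crop_land_per_kg <- function(yield) {
  if (any(yield <= 0)) stop("yield must be > 0", call. = FALSE)
  10000 / (yield * 1000)
}

#' Price-based co-product allocation shares
#'
#' Splits a crop's land footprint among co-products in proportion to each
#' co-product's share of total market value: `share_i = m_i p_i /
#' sum_j m_j p_j`. Shares always sum to 1.
#'
#' @param mass_fractions named numeric vector of co-product mass fractions.
#' @param prices named numeric vector, $ per kg, same names.
#' @return named numeric vector of allocation shares.
#' @examples
#' price_allocation(c(oil = 0.20, meal = 0.80), c(oil = 0.87, meal = 0.33))
#' @export
price_allocation <- function(mass_fractions, prices) {
  if (length(mass_fractions) < 1L) stop("need >= 1 component",
                                        call. = FALSE)
  if (!is.null(names(mass_fractions))) {
    prices <- prices[names(mass_fractions)]
  }
  if (any(mass_fractions < 0) || any(prices < 0)) {
    stop("fractions and prices must be >= 0", call. = FALSE)
  }
  value <- mass_fractions * prices
  total <- sum(value)
  if (total <= 0) stop("total co-product value must be > 0", call. = FALSE)
  value / total
}

.chain_allocation_share <- function(chain) {
  if (!is.na(chain$allocation_share)) return(chain$allocation_share)
  shares <- price_allocation(chain$component_fractions,
                             chain$component_prices)
  unname(shares[chain$usable_component])
}

#' Soy land requirement per kg cultured meat
#'
#' Land to grow the soybeans supplying the hydrolysate protein for one kg
#' of meat, after price-based meal/oil allocation. Two chain
#' interpretations are supported:
#' \describe{
#'   \item{`as_printed`}{soybean mass = protein need / meal protein
#'     content (0.48); the meal mass fraction and hydrolysate recovery
#'     cancel out of the published arithmetic.}
#'   \item{`stated_chain`}{soybean mass = protein need /
#'     (meal fraction x meal protein x recovery), the full narrative
#'     processing chain; gives a larger footprint whenever the meal
#'     fraction and recovery are below 1.}
#' }
#'
#' @param chain a soy [feedstock_chain()].
#' @param protein_need kg protein per kg meat (see
#'   [protein_feed_per_kg()]).
#' @param chain_mode overrides the chain's mode if given.
#' @return m2 per kg meat.
#' @export
soy_land_per_kg_cm <- function(chain, protein_need, chain_mode = NULL) {
  stopifnot(inherits(chain, "feedstock_chain"))
  mode <- chain_mode %||% chain$chain_mode
  denom <- switch(mode,
    as_printed = chain$nutrient_fraction,
    stated_chain = chain$component_fractions[[chain$usable_component]] *
      chain$nutrient_fraction * chain$recovery_fraction,
    stop("unknown chain_mode: ", mode, call. = FALSE)
  )
  if (denom <= 0) stop("chain denominator must be > 0", call. = FALSE)
  crop_kg <- protein_need / denom
  crop_kg * crop_land_per_kg(chain$yield) * .chain_allocation_share(chain)
}

#' Corn land requirement per kg cultured meat
#'
#' Land to grow the corn supplying glucose (via wet-milled starch) for one
#' kg of meat: `glucose need / starch fraction` kg corn, times land per kg
#' corn, times the starch allocation share.
#'
#' @param chain a corn [feedstock_chain()].
#' @param glucose_need kg glucose per kg meat.
#' @return m2 per kg meat.
#' @export
corn_land_per_kg_cm <- function(chain, glucose_need) {
  stopifnot(inherits(chain, "feedstock_chain"))
  starch <- chain$nutrient_fraction
  if (starch <= 0) stop("starch fraction must be > 0", call. = FALSE)
  corn_kg <- glucose_need / starch
  corn_kg * crop_land_per_kg(chain$yield) * .chain_allocation_share(chain)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cultured-meat land use ledger
#'
#' Combines the protein (soy) and energy (corn) land requirements into a
#' total footprint per kg meat, with the intermediate quantities kept for
#' inspection.
#'
#' @param scenario output of [load_scenario()].
#' @return A list of class `land_use_result`: `protein_land`,
#'   `energy_land`, `total_land` (m2 per kg meat) and a `ledger` list
#'   (protein need, glucose need, crop masses, allocation shares).
#' @export
cm_land_use <- function(scenario = load_scenario()) {
  cm <- scenario$cm_batch
  soy <- scenario$feedstocks$soy
  corn <- scenario$feedstocks$corn
  protein_need <- protein_feed_per_kg(cm$meat_protein_fraction,
                                      cm$protein_conversion_efficiency)
  glucose_need <- glucose_feed_per_kg(cm$meat_energy_density,
                                      cm$calorie_conversion_efficiency,
                                      cm$glucose_energy_density)
  protein_land <- soy_land_per_kg_cm(soy, protein_need)
  energy_land <- corn_land_per_kg_cm(corn, glucose_need)
  soy_denom <- switch(soy$chain_mode,
    as_printed = soy$nutrient_fraction,
    stated_chain = soy$component_fractions[[soy$usable_component]] *
      soy$nutrient_fraction * soy$recovery_fraction)
  structure(
    list(
      protein_land = protein_land,
      energy_land = energy_land,
      total_land = protein_land + energy_land,
      ledger = list(
        protein_need = protein_need,
        glucose_need = glucose_need,
        soy_kg = protein_need / soy_denom,
        corn_kg = glucose_need / corn$nutrient_fraction,
        soy_allocation = .chain_allocation_share(soy),
        corn_allocation = .chain_allocation_share(corn),
        soy_chain_mode = soy$chain_mode
      )
    ),
    class = "land_use_result"
  )
}

#' Areal protein and energy productivity from land use
#'
#' Converts a land-use intensity into nutrient output per unit cropland:
#' `protein productivity = 1,000 x protein fraction / land use`
#' (g protein m^-2 yr^-1) and `energy productivity = kcal per kg x
#' 4.184 / 1,000 / land use` (MJ m^-2 yr^-1).
#'
#' @param land_use m2 per kg product per year, > 0.
#' @param protein_fraction kg protein per kg product.
#' @param energy kcal per kg product.
#' @param source character label carried through.
#' @param land_use_range optional `c(min, max)` m2 per kg per year.
#' @return A one-row data frame: `source`, `land_use`,
#'   `protein_productivity`, `energy_productivity`, `land_use_min`,
#'   `land_use_max`, `protein_productivity_min/max`,
#'   `energy_productivity_min/max` (min productivity from max land use).
#' @export
landuse_to_productivity <- function(land_use, protein_fraction, energy,
                                    source = NA_character_,
                                    land_use_range = NULL) {
  if (any(land_use <= 0)) stop("land_use must be > 0", call. = FALSE)
  k <- cm_constants()
  pp <- function(lu) 1000 * protein_fraction / lu
  ep <- function(lu) energy * k$kj_per_kcal / 1000 / lu
  rng <- land_use_range %||% c(NA_real_, NA_real_)
  data.frame(
    source = source,
    land_use = land_use,
    protein_productivity = pp(land_use),
    energy_productivity = ep(land_use),
    land_use_min = rng[1],
    land_use_max = rng[2],
    protein_productivity_min = if (is.na(rng[2])) NA_real_ else pp(rng[2]),
    protein_productivity_max = if (is.na(rng[1])) NA_real_ else pp(rng[1]),
    energy_productivity_min = if (is.na(rng[2])) NA_real_ else ep(rng[2]),
    energy_productivity_max = if (is.na(rng[1])) NA_real_ else ep(rng[1]),
    stringsAsFactors = FALSE
  )
}

# literature land-use comparators (m2 kg^-1 yr^-1) with midpoint rule for
# ranges, plus product composition used to convert them to productivities
.livestock_land_presets <- function() {
  list(
    beef = list(range = c(15, 429), protein = 0.22, energy = 1270),
    swine = list(range = c(8, 15), protein = 0.17, energy = 2630),
    broiler = list(range = c(8.7, 8.7), protein = 0.17, energy = 1430)
  )
}

#' Areal productivity comparison table
#'
#' One row per production system: cultured meat (modelled land use from
#' [cm_land_use()]) and the literature-derived swine, beef, and broiler
#' land uses (midpoints of published ranges), each converted to protein
#' and energy areal productivities.
#'
#' Beef product composition uses 97% lean ground beef; its energy density
#' is not published alongside the land-use figures, so a configurable
#' default of 1,270 kcal/kg (~5.3 MJ/kg) is used.
#'
#' @param scenario output of [load_scenario()].
#' @param beef_energy kcal per kg, default 1270.
#' @return data frame, one row per system.
#' @export
areal_table <- function(scenario = load_scenario(), beef_energy = 1270) {
  lu <- cm_land_use(scenario)
  cm <- scenario$cm_batch
  presets <- .livestock_land_presets()
  presets$beef$energy <- beef_energy
  rows <- lapply(names(presets), function(sp) {
    p <- presets[[sp]]
    landuse_to_productivity(mean(p$range), p$protein, p$energy,
                            source = sp, land_use_range = p$range)
  })
  rows <- c(rows, list(
    landuse_to_productivity(lu$total_land, cm$meat_protein_fraction,
                            cm$meat_energy_density,
                            source = "cultured meat")
  ))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
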