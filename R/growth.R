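#' Specific growth rate
#'
#' Exponential growth constant `mu = ln(final/initial) / duration`, per
#' day. The basis (live mass, edible mass, or cell count) is the caller's
#' choice; both endpoints must use the same basis.
#'
#' @param initial,final masses (kg) or cell counts, both > 0.
#' @param duration days, > 0.
#' @return growth rate, day^-1.
#' @examples
#' specific_growth_rate(1.4, 130, 180)  # swine, 0.025 day^-1
#' @export
specific_growth_rate <- function(initial, final, duration) {
  if (any(initial <= 0) || any(final <= 0)) {
    stop("masses must be > 0", call. = FALSE)
  }
  if (any(duration <= 0)) stop("duration must be > 0", call. = FALSE)
  log(final / initial) / duration
}

#' Average daily gain
#'
#' `(live - birth) / duration`, kg per day.
#'
#' @param birth,live kg.
#' @param duration days, > 0.
#' @return kg per day.
#' @export
average_daily_gain <- function(birth, live, duration) {
  if (any(duration <= 0)) stop("duration must be > 0", call. = FALSE)
  (live - birth) / duration
}

#' Feed use and protein conversion for a conventional animal
#'
#' Endpoint arithmetic over an [animal_spec()]: total feed is live weight
#' times feed conversion ratio; protein fed is total feed times the diet
#' protein fraction; meat output is live weight times the edible fraction;
#' protein output is meat output times the meat protein fraction; protein
#' conversion efficiency (PCE) is protein out over protein in.
#'
#' @param spec an [animal_spec()].
#' @param mu_basis `"live"` (default) computes the specific growth rate
#'   from birth and live weights; `"edible"` scales both endpoints by the
#'   edible fraction (which leaves the rate unchanged only when the
#'   fraction applies to both endpoints; offered for completeness).
#' @return A one-row data frame of class `growth_metrics` with columns
#'   `species`, `birth_weight`, `live_weight`, `edible_fraction`,
#'   `meat_output`, `meat_protein_fraction`, `meat_moisture_fraction`,
#'   `growth_time`, `average_daily_gain`, `specific_growth_rate`,
#'   `feed_conversion_ratio`, `total_feed`, `diet_protein_fraction`,
#'   `protein_fed`, `protein_output`, `pce`.
#' @export
feed_and_protein <- function(spec, mu_basis = c("live", "edible")) {
  stopifnot(inherits(spec, "animal_spec"))
  mu_basis <- match.arg(mu_basis)
  total_feed <- spec$live_weight * spec$feed_conversion_ratio
  protein_fed <- total_feed * spec$diet_protein_fraction
  meat_output <- spec$live_weight * spec$edible_fraction
  protein_output <- meat_output * spec$meat_protein_fraction
  if (protein_fed <= 0) stop("protein_fed must be > 0", call. = FALSE)
  mi <- spec$birth_weight
  mf <- spec$live_weight
  if (mu_basis == "edible") {
    mi <- mi * spec$edible_fraction
    mf <- mf * spec$edible_fraction
  }
  mu <- if (mi > 0) {
    specific_growth_rate(mi, mf, spec$growth_time)
  } else {
    NA_real_
  }
  out <- data.frame(
    species = spec$species,
    birth_weight = spec$birth_weight,
    live_weight = spec$live_weight,
    edible_fraction = spec$edible_fraction,
    meat_output = meat_output,
    meat_protein_fraction = spec$meat_protein_fraction,
    meat_moisture_fraction = spec$meat_moisture_fraction,
    growth_time = spec$growth_time,
    average_daily_gain = average_daily_gain(spec$birth_weight,
                                            spec$live_weight,
                                            spec$growth_time),
    specific_growth_rate = mu,
    feed_conversion_ratio = spec$feed_conversion_ratio,
    total_feed = total_feed,
    diet_protein_fraction = spec$diet_protein_fraction,
    protein_fed = protein_fed,
    protein_output = protein_output,
    pce = protein_output / protein_fed,
    stringsAsFactors = FALSE
  )
  class(out) <- c("growth_metrics", class(out))
  out
}

#' Growth and feed metrics for a cultured-meat batch
#'
#' Builds the cultured-meat column of the growth comparison table.
#' Protein fed is the batch protein output divided by the protein
#' conversion efficiency; total feed is protein feed plus glucose feed;
#' the feed conversion ratio is total feed over harvested meat mass. The
#' specific growth rate defaults to the proliferation-phase cell-density
#' basis (`ln(final/initial density) / proliferation days`); the alternate
#' `"mass"` basis uses inoculum and harvest masses over the whole batch.
#'
#' @param spec a [cm_batch_spec()].
#' @param glucose_feed kg glucose per batch; computed from the spec's
#'   energy parameters when omitted (see [glucose_feed_per_kg()]).
#' @param mu_basis `"density"` (default) or `"mass"`.
#' @return A one-row `growth_metrics` data frame (same columns as
#'   [feed_and_protein()]).
#' @export
cm_growth_metrics <- function(spec, glucose_feed = NULL,
                              mu_basis = c("density", "mass")) {
  stopifnot(inherits(spec, "cm_batch_spec"))
  mu_basis <- match.arg(mu_basis)
  if (is.null(glucose_feed)) {
    glucose_feed <- glucose_feed_per_kg(
      spec$meat_energy_density,
      spec$calorie_conversion_efficiency,
      spec$glucose_energy_density
    ) * spec$batch_meat_mass
  }
  protein_output <- spec$batch_meat_mass * spec$meat_protein_fraction
  protein_fed <- protein_output / spec$protein_conversion_efficiency
  total_feed <- protein_fed + glucose_feed
  growth_days <- (spec$proliferation_duration +
                    spec$maturation_duration) / 24
  birth <- inoculum_mass(spec)
  mu <- if (mu_basis == "density") {
    specific_growth_rate(spec$initial_cell_density,
                         spec$final_cell_density,
                         spec$proliferation_duration / 24)
  } else {
    specific_growth_rate(birth, spec$batch_meat_mass, growth_days)
  }
  out <- data.frame(
    species = "cultured meat",
    birth_weight = birth,
    live_weight = spec$batch_meat_mass,
    edible_fraction = 1,
    meat_output = spec$batch_meat_mass,
    meat_protein_fraction = spec$meat_protein_fraction,
    meat_moisture_fraction = spec$meat_moisture_fraction,
    growth_time = growth_days,
    average_daily_gain = average_daily_gain(birth, spec$batch_meat_mass,
                                            growth_days),
    specific_growth_rate = mu,
    feed_conversion_ratio = total_feed / spec$batch_meat_mass,
    total_feed = total_feed,
    diet_protein_fraction = protein_fed / total_feed,
    protein_fed = protein_fed,
    protein_output = protein_output,
    pce = spec$protein_conversion_efficiency,
    stringsAsFactors = FALSE
  )
  class(out) <- c("growth_metrics", class(out))
  out
}

#' Growth comparison table
#'
#' One row per production system (swine, beef, broiler, cultured meat),
#' reconstructing the growth/feed-use comparison from the packaged presets
#' or a loaded scenario.
#'
#' @param scenario output of [load_scenario()]; defaults to all presets.
#' @return a `growth_metrics` data frame with one row per system.
#' @export
growth_table <- function(scenario = load_scenario()) {
  rows <- lapply(scenario$animals, feed_and_protein)
  rows$cm <- cm_growth_metrics(scenario$cm_batch)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
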