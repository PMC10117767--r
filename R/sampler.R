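#' Define a sampling range for one model parameter
#'
#' @param name parameter name; must be one of the sampleable parameters
#'   (see [default_parameter_ranges()]).
#' @param low,high range bounds, `low <= high`.
#' @param distribution `"uniform"`, `"log-uniform"` (requires `low > 0`),
#'   or `"triangular"` (with `mode`).
#' @param mode mode for the triangular distribution.
#' @param units free-text unit annotation.
#' @return An object of class `parameter_range`.
#' @export
parameter_range <- function(name, low, high,
                            distribution = c("uniform", "log-uniform",
                                             "triangular"),
                            mode = (low + high) / 2, units = "") {
  distribution <- match.arg(distribution)
  if (low > high) stop("low must be <= high for '", name, "'",
                       call. = FALSE)
  if (distribution == "log-uniform" && low <= 0) {
    stop("log-uniform range requires low > 0 for '", name, "'",
         call. = FALSE)
  }
  if (distribution == "triangular" && (mode < low || mode > high)) {
    stop("triangular mode must lie in [low, high] for '", name, "'",
         call. = FALSE)
  }
  structure(list(name = name, low = low, high = high,
                 distribution = distribution, mode = mode, units = units),
            class = "parameter_range")
}

# parameters that may be sampled and where they live
.sampleable <- c(
  initial_cell_density = "cm_batch",
  final_cell_density = "cm_batch",
  cell_wet_mass = "cm_batch",
  proliferation_duration = "cm_batch",
  maturation_duration = "cm_batch",
  reactor_volume = "cm_batch",
  protein_conversion_efficiency = "cm_batch",
  calorie_conversion_efficiency = "cm_batch",
  oxygen_uptake_rate = "cm_batch",
  meat_price = "economics",
  n_fertilizer_price = "economics"
)

#' Default Monte-Carlo ranges over published parameter spreads
#'
#' Ranges spanning the cultured-meat batch parameters reported across
#' published production models (cell densities, phase lengths, per-cell
#' mass, reactor size, conversion efficiencies) plus the meat-price and
#' nitrogen-fertilizer-price spreads. Cell densities use log-uniform
#' draws because the published spreads cover more than an order of
#' magnitude; everything else is uniform. These defaults are this
#' package's own choice: the source analyses publish ranges but no
#' distributions.
#'
#' @return named list of [parameter_range()] objects.
#' @export
default_parameter_ranges <- function() {
  r <- list(
    parameter_range("initial_cell_density", 1e5, 2e6, "log-uniform",
                    units = "cells/ml"),
    parameter_range("final_cell_density", 4e6, 2e8, "log-uniform",
                    units = "cells/ml"),
    parameter_range("cell_wet_mass", 3e-9, 4.4e-9, units = "g"),
    parameter_range("proliferation_duration", 48, 240, units = "h"),
    parameter_range("maturation_duration", 24, 240, units = "h"),
    parameter_range("reactor_volume", 1, 20, units = "m3"),
    parameter_range("protein_conversion_efficiency", 0.17, 0.33),
    parameter_range("calorie_conversion_efficiency", 0.17, 0.33),
    parameter_range("meat_price", 10, 25, units = "$/kg"),
    parameter_range("n_fertilizer_price", 1, 3, units = "$/kg N")
  )
  setNames(r, vapply(r, `[[`, "", "name"))
}

.draw_one <- function(range, u) {
  switch(range$distribution,
    uniform = range$low + u * (range$high - range$low),
    "log-uniform" = exp(log(range$low) +
                          u * (log(range$high) - log(range$low))),
    triangular = {
      if (range$high == range$low) return(range$low)
      fc <- (range$mode - range$low) / (range$high - range$low)
      ifelse(u < fc,
             range$low + sqrt(u * (range$high - range$low) *
                                (range$mode - range$low)),
             range$high - sqrt((1 - u) * (range$high - range$low) *
                                 (range$high - range$mode)))
    }
  )
}

# rebuild a batch spec around sampled fields; harvested mass follows the
# sampled densities and the media water scales with it at the baseline
# water-per-kg intensity, so every draw is internally consistent
.spec_from_draw <- function(params, base = preset_cm_batch()) {
  fields <- unclass(base)
  water_per_kg <- base$water_per_batch / base$batch_meat_mass
  cm_names <- intersect(names(params),
                        names(.sampleable)[.sampleable == "cm_batch"])
  fields[cm_names] <- params[cm_names]
  mass <- fields$final_cell_density * fields$reactor_volume * 1e6 *
    fields$cell_wet_mass / 1000
  fields$batch_meat_mass <- mass
  fields$water_per_batch <- water_per_kg * mass
  fields$cleaning_water_per_batch <- base$cleaning_water_per_batch /
    base$batch_meat_mass * mass
  suppressWarnings(do.call(cm_batch_spec, fields))
}

#' Draw a seeded ensemble of production scenarios
#'
#' Samples `n` parameter sets from the given ranges, rebuilding a
#' consistent batch spec for each draw (harvest mass from the sampled
#' densities, water scaled at the baseline intensity). Draws that violate
#' joint constraints (final density below initial density) are resampled
#' up to `max_retries` times per slot.
#'
#' @param n number of draws, >= 1.
#' @param seed integer RNG seed; fixed seed gives a bit-identical
#'   ensemble.
#' @param ranges named list of [parameter_range()]; default
#'   [default_parameter_ranges()].
#' @param base baseline [cm_batch_spec()] supplying unsampled fields.
#' @param max_retries resample cap per draw.
#' @return An object of class `scenario_ensemble`: list with `seed`,
#'   `n_draws`, `params` (n x p matrix of sampled values), and `specs`
#'   (list of [cm_batch_spec()]).
#' @export
sample_scenarios <- function(n, seed, ranges = default_parameter_ranges(),
                             base = preset_cm_batch(), max_retries = 100) {
  stopifnot(n >= 1)
  for (r in ranges) {
    if (!inherits(r, "parameter_range")) {
      stop("ranges must be parameter_range objects", call. = FALSE)
    }
    if (!r$name %in% names(.sampleable)) {
      stop("unknown sampleable parameter: ", r$name, call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  pnames <- vapply(ranges, `[[`, "", "name")
  draw_row <- function() {
    u <- stats::runif(length(ranges))
    vapply(seq_along(ranges), function(i) .draw_one(ranges[[i]], u[i]),
           numeric(1))
  }
  params <- matrix(NA_real_, nrow = n, ncol = length(ranges),
                   dimnames = list(NULL, pnames))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      row <- setNames(draw_row(), pnames)
      lo <- if ("initial_cell_density" %in% pnames) {
        row[["initial_cell_density"]]
      } else base$initial_cell_density
      hi <- if ("final_cell_density" %in% pnames) {
        row[["final_cell_density"]]
      } else base$final_cell_density
      if (hi >= lo) { ok <- TRUE; break }
    }
    if (!ok) stop("resample cap reached for joint density constraint",
                  call. = FALSE)
    params[i, ] <- row
  }
  specs <- lapply(seq_len(n), function(i) {
    .spec_from_draw(as.list(params[i, , drop = TRUE]), base)
  })
  structure(list(seed = as.integer(seed), n_draws = n, params = params,
                 specs = specs),
            class = "scenario_ensemble")
}

# all registered output metrics for one scenario draw
.pipeline_metrics <- function(spec, price, revenue_target,
                              econ = preset_econ_costs()) {
  scen <- list(
    cm_batch = spec,
    feedstocks = list(soy = preset_feedstock("soy"),
                      corn = preset_feedstock("corn")),
    economics = econ,
    animals = preset_animal("all")
  )
  lu <- cm_land_use(scen)
  bb <- batch_balance(spec)
  sc <- scale_scenario(spec, price, revenue_target, bb)
  geom <- application_area(sc$annual_nitrogen, econ$n_application_rate,
                           econ$corn_land_fraction)
  app <- application_cost(sc$annual_wastewater, geom$adjusted_area, econ)
  wwt <- wwt_cost(sc$annual_nitrogen, sc$annual_cod, econ, sc$annual_mass)
  part <- cm_partition(spec$protein_conversion_efficiency)
  c(
    total_land = lu$total_land,
    annual_nitrogen = sc$annual_nitrogen,
    annual_cod = sc$annual_cod,
    batches_per_year = sc$batches_per_year,
    reactors = sc$reactors,
    specific_application_cost = app$total_cost / sc$annual_mass,
    specific_wwt_cost = wwt$specific_total,
    lost_fraction = part$lost_fraction,
    nitrogen_concentration = bb$nitrogen_concentration
  )
}

.metric_names <- c("total_land", "annual_nitrogen", "annual_cod",
                   "batches_per_year", "reactors",
                   "specific_application_cost", "specific_wwt_cost",
                   "lost_fraction", "nitrogen_concentration")

#' Run the full pipeline over an ensemble
#'
#' Evaluates every registered output metric (land use, annual nitrogen
#' and COD, batch/reactor counts, specific application and treatment
#' costs, lost-N fraction, spent-media N concentration) for each draw.
#' Per-draw failures are recorded, not fatal; only an all-draw failure
#' aborts.
#'
#' @param ensemble a [sample_scenarios()] result.
#' @param price $ per kg meat; per-draw sampled `meat_price` is used when
#'   present, otherwise this value.
#' @param revenue_target $ per year.
#' @param econ an [econ_costs()].
#' @return An object of class `ensemble_result`: `seed`, `n_draws`,
#'   `draws` (data frame of inputs and outputs, one row per draw, with an
#'   `error` column), and `summary` (quantiles of each metric at 2.5, 25,
#'   50, 75, 97.5%).
#' @export
run_ensemble <- function(ensemble, price = 25, revenue_target = 1e7,
                         econ = preset_econ_costs()) {
  stopifnot(inherits(ensemble, "scenario_ensemble"),
            ensemble$n_draws >= 1)
  rows <- vector("list", ensemble$n_draws)
  errors <- character(ensemble$n_draws)
  for (i in seq_len(ensemble$n_draws)) {
    p <- if ("meat_price" %in% colnames(ensemble$params)) {
      unname(ensemble$params[i, "meat_price"])
    } else price
    rows[[i]] <- tryCatch(
      .pipeline_metrics(ensemble$specs[[i]], p, revenue_target, econ),
      error = function(e) {
        errors[i] <<- conditionMessage(e)
        setNames(rep(NA_real_, length(.metric_names)), .metric_names)
      }
    )
  }
  out <- as.data.frame(do.call(rbind, rows))
  # the metric columns must be exactly the registered names; a named
  # scalar leaking into c() inside the pipeline would silently detach
  # the summary from the draws
  stopifnot(identical(colnames(out), .metric_names))
  if (all(nzchar(errors))) {
    stop("all draws failed; first cause: ", errors[1], call. = FALSE)
  }
  draws <- cbind(as.data.frame(ensemble$params), out)
  draws$error <- ifelse(nzchar(errors), errors, NA_character_)
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  summ <- vapply(.metric_names, function(m) {
    quantile(out[[m]], qs, na.rm = TRUE)
  }, numeric(length(qs)))
  structure(list(seed = ensemble$seed, n_draws = ensemble$n_draws,
                 draws = draws, summary = t(summ)),
            class = "ensemble_result")
}

#' One-at-a-time sensitivity (tornado) analysis
#'
#' Evaluates one output metric with each parameter set to its range
#' endpoints while all others stay at baseline, and ranks parameters by
#' the absolute swing.
#'
#' @param metric one of `total_land`, `annual_nitrogen`, `annual_cod`,
#'   `batches_per_year`, `reactors`, `specific_application_cost`,
#'   `specific_wwt_cost`, `lost_fraction`, `nitrogen_concentration`.
#' @param ranges named list of [parameter_range()].
#' @param base baseline [cm_batch_spec()].
#' @param price,revenue_target production scenario; a `meat_price` range
#'   overrides `price` at its endpoints.
#' @param econ an [econ_costs()].
#' @return data frame sorted by decreasing `abs_swing`: `parameter`,
#'   `low`, `high`, `metric_at_low`, `metric_at_high`, `swing`,
#'   `abs_swing`.
#' @export
tornado <- function(metric, ranges = default_parameter_ranges(),
                    base = preset_cm_batch(), price = 25,
                    revenue_target = 1e7, econ = preset_econ_costs()) {
  if (!metric %in% .metric_names) {
    stop("unregistered metric '", metric, "'; choose one of: ",
         paste(.metric_names, collapse = ", "), call. = FALSE)
  }
  eval_at <- function(name, value) {
    p <- price
    spec <- base
    if (name == "meat_price") {
      p <- value
    } else if (name == "n_fertilizer_price") {
      # informational range; no registered metric depends on it
    } else {
      params <- setNames(list(value), name)
      spec <- .spec_from_draw(params, base)
      # keep the baseline harvest mass when the sampled field does not
      # determine it, so single-parameter sweeps stay interpretable
      if (!name %in% c("final_cell_density", "cell_wet_mass",
                       "reactor_volume")) {
        fields <- unclass(base)
        fields[[name]] <- value
        spec <- suppressWarnings(do.call(cm_batch_spec, fields))
      }
    }
    .pipeline_metrics(spec, p, revenue_target, econ)[[metric]]
  }
  rows <- lapply(ranges, function(r) {
    lo <- eval_at(r$name, r$low)
    hi <- eval_at(r$name, r$high)
    data.frame(parameter = r$name, low = r$low, high = r$high,
               metric_at_low = lo, metric_at_high = hi,
               swing = hi - lo, abs_swing = abs(hi - lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$abs_swing), ]
  rownames(out) <- NULL
  out
}
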