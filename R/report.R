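#' Annual production-scenario table
#'
#' The spent-media nitrogen/COD production and management costs for the
#' given meat-price scenarios: annual meat mass, batch and reactor
#' counts, waste nitrogen and COD, wastewater volume, land-application
#' geometry and cost, wastewater-treatment cost, and the specific
#' ($ per kg meat) costs.
#'
#' @param scenario output of [load_scenario()].
#' @param prices $ per kg meat, one column per price.
#' @param revenue_target $ per year.
#' @return data frame, one row per price scenario.
#' @export
scenario_table <- function(scenario = load_scenario(), prices = c(25, 10),
                           revenue_target = 1e7) {
  econ <- scenario$economics
  bb <- batch_balance(scenario$cm_batch)
  rows <- lapply(prices, function(p) {
    sc <- scale_scenario(scenario$cm_batch, p, revenue_target, bb)
    geom <- application_area(sc$annual_nitrogen, econ$n_application_rate,
                             econ$corn_land_fraction)
    app <- application_cost(sc$annual_wastewater, geom$adjusted_area,
                            econ)
    wwt <- wwt_cost(sc$annual_nitrogen, sc$annual_cod, econ,
                    sc$annual_mass)
    data.frame(
      meat_price = p,
      annual_mass = sc$annual_mass,
      batches_per_year = sc$batches_per_year,
      reactors = sc$reactors,
      annual_nitrogen = sc$annual_nitrogen,
      annual_cod = sc$annual_cod,
      annual_wastewater = sc$annual_wastewater,
      required_area_ha = geom$required_area,
      adjusted_area_ha = geom$adjusted_area,
      service_radius_km = geom$service_radius_km,
      fraction_beyond_threshold = app$fraction_beyond,
      application_cost = app$total_cost,
      wwt_cost = wwt$total_cost,
      specific_application_cost = app$total_cost / sc$annual_mass,
      specific_wwt_cost = wwt$specific_total,
      specific_wwt_n = wwt$specific_n,
      specific_wwt_cod = wwt$specific_cod,
      person_equivalents = person_equivalents(sc$annual_nitrogen),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the full report bundle
#'
#' Runs every pipeline stage for one scenario configuration and collects
#' the result tables: growth/feed metrics, areal productivities, the
#' annual production scenarios, the nutrient-management cost comparison,
#' and the nitrogen-use-efficiency partitions with parity recovery
#' targets. Deterministic for a fixed configuration.
#'
#' @param config scenario config (path, YAML text, list, or `NULL` for
#'   presets); see [load_scenario()].
#' @param prices $ per kg meat for the production scenarios.
#' @param revenue_target $ per year.
#' @return An object of class `report_bundle`: `growth`, `areal`,
#'   `scenarios`, `costs`, `nue_partitions`, `nue_parity` (data frames)
#'   plus `metadata` (timestamp-free: prices, revenue target, package
#'   version).
#' @export
build_report <- function(config = NULL, prices = c(25, 10),
                         revenue_target = 1e7) {
  scenario <- load_scenario(config)
  nue <- nue_table(scenario)
  structure(
    list(
      growth = growth_table(scenario),
      areal = areal_table(scenario),
      scenarios = scenario_table(scenario, prices, revenue_target),
      costs = cost_table(scenario, prices, revenue_target),
      nue_partitions = nue$partitions,
      nue_parity = nue$parity,
      metadata = list(
        prices = prices,
        revenue_target = revenue_target,
        package_version = as.character(
          utils::packageVersion("cmnutricycle"))
      )
    ),
    class = "report_bundle"
  )
}

#' Write report tables to disk
#'
#' One CSV per table plus a metadata JSON, or a single nested JSON
#' document. Numeric values are written at full precision; re-reading a
#' CSV reproduces the bundle values.
#'
#' @param bundle a [build_report()] result.
#' @param dir output directory; created if absent.
#' @param format `"csv"` or `"json"`.
#' @return invisibly, the written file paths.
#' @export
write_tables <- function(bundle, dir, format = c("csv", "json")) {
  stopifnot(inherits(bundle, "report_bundle"))
  format <- match.arg(format)
  tables <- bundle[setdiff(names(bundle), "metadata")]
  if (!length(tables) || any(vapply(tables, nrow, 0L) == 0L)) {
    stop("report bundle is empty or has empty tables; nothing written",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "csv") {
    paths <- character(0)
    for (nm in names(tables)) {
      path <- file.path(dir, paste0(nm, ".csv"))
      write.csv(tables[[nm]], path, row.names = FALSE, quote = TRUE)
      paths <- c(paths, path)
    }
    meta_path <- file.path(dir, "metadata.json")
    jsonlite::write_json(bundle$metadata, meta_path, auto_unbox = TRUE,
                         digits = NA)
    invisible(c(paths, meta_path))
  } else {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    invisible(path)
  }
}
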