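#' Assemble and validate the projection inputs for a world
#'
#' Bundles everything [run_scenario()] needs. Countries missing from any
#' required table are dropped from all scenarios symmetrically (with a
#' warning), so cross-scenario comparisons always cover the same set.
#'
#' @param base Tibble, one row per country: `country_id, group, area_2018,
#'   demand_2018` (kcal/person/day), `population_2018, gdp_2018,
#'   yield_2018` (kcal/ha), `trend_slope` (kcal/ha/yr), `ceiling_2050,
#'   ceiling_2100` (kcal/ha), `climate_multiplier_2050,
#'   climate_multiplier_2100, kcal_per_usd`.
#' @param population Tibble `country_id, horizon, variant, population` with
#'   variants `median` and `accelerated` at each horizon.
#' @param net_exports Tibble `country_id, scenario, horizon,
#'   net_exports_usd` (the exogenous trade-model output).
#' @param demand_model A [demand_model()].
#' @param growth_model A [growth_model()].
#' @param demand_paths Optional tibble `country_id, horizon, scenario,
#'   demand_daily` overriding the modelled demand (e.g. pinned inputs).
#' @param base_year Base year for areas, demand ramps, and conversion
#'   ratios; default 2018.
#' @return A `world_inputs` object.
#' @export
world_inputs <- function(base, population, net_exports, demand_model,
                         growth_model, demand_paths = NULL,
                         base_year = 2018) {
  req <- c("country_id", "group", "area_2018", "demand_2018",
           "population_2018", "gdp_2018", "yield_2018", "trend_slope",
           "ceiling_2050", "ceiling_2100", "climate_multiplier_2050",
           "climate_multiplier_2100", "kcal_per_usd")
  missing <- setdiff(req, names(base))
  if (length(missing)) {
    stop("base table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(inherits(demand_model, "demand_model"),
            inherits(growth_model, "growth_model"))
  have_pop <- population |>
    dplyr::group_by(country_id) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(n == length(unique(population$horizon)) *
                    length(unique(population$variant))) |>
    dplyr::pull(country_id)
  have_trade <- unique(net_exports$country_id)
  keep <- Reduce(intersect, list(base$country_id, have_pop, have_trade))
  dropped <- setdiff(base$country_id, keep)
  if (length(dropped)) {
    warning(length(dropped), " country(ies) lacking projection inputs ",
            "excluded from all scenarios: ",
            paste(utils::head(dropped, 10), collapse = ", "), call. = FALSE)
  }
  if (!length(keep)) stop("no country has complete projection inputs",
                          call. = FALSE)
  structure(
    list(base = base[base$country_id %in% keep, ],
         population = population[population$country_id %in% keep, ],
         net_exports = net_exports[net_exports$country_id %in% keep, ],
         demand_model = demand_model, growth_model = growth_model,
         demand_paths = demand_paths, base_year = base_year),
    class = "world_inputs"
  )
}

#' @export
print.world_inputs <- function(x, ...) {
  cat(sprintf("<world_inputs> %d countries, base year %d\n",
              nrow(x$base), x$base_year))
  cat("  scenarios with trade tables: ",
      paste(unique(x$net_exports$scenario), collapse = ", "), "\n")
  invisible(x)
}

#' Configure a projection scenario
#'
#' The four named scenarios are shorthand for toggle sets on three
#' accelerated-development factors — income-driven demand growth
#' (`demand_boost`), the low-fertility population variant
#' (`population_accelerated`), and the accelerated yield rule
#' (`yield_accelerated`) — plus the higher-income demand cap
#' (`demand_capped`):
#' \itemize{
#'   \item `BAU`: all toggles off.
#'   \item `reduced_demand`: demand cap only.
#'   \item `accelerated`: all three development toggles on.
#'   \item `equitable`: `reduced_demand` composed with `accelerated`.
#' }
#' Factor-permutation runs ([run_permutations()]) override individual
#' toggles.
#'
#' @param scenario One of `"BAU"`, `"reduced_demand"`, `"accelerated"`,
#'   `"equitable"`.
#' @param frictionless Also compute the frictionless-trade global clearing?
#' @param toggles Optional named logical vector overriding any of
#'   `demand_boost`, `population_accelerated`, `yield_accelerated`.
#' @param gdp_threshold Acceleration threshold, 2010 USD; default 8,100.
#' @param demand_target Reduced-demand endpoint, kcal/person/day; default
#'   5,000.
#' @param horizons Projection years; default `c(2050, 2100)`.
#' @param trade_scenario Which trade table to read; defaults to the
#'   scenario id.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(scenario = c("BAU", "reduced_demand",
                                         "accelerated", "equitable"),
                            frictionless = FALSE, toggles = NULL,
                            gdp_threshold = 8100, demand_target = 5000,
                            horizons = c(2050, 2100),
                            trade_scenario = NULL) {
  scenario <- match.arg(scenario)
  accel <- scenario %in% c("accelerated", "equitable")
  tg <- c(demand_boost = accel, population_accelerated = accel,
          yield_accelerated = accel)
  if (!is.null(toggles)) {
    stopifnot(is.logical(toggles), all(names(toggles) %in% names(tg)))
    tg[names(toggles)] <- toggles
  }
  structure(
    list(scenario = scenario, frictionless = frictionless, toggles = tg,
         demand_capped = scenario %in% c("reduced_demand", "equitable"),
         gdp_threshold = gdp_threshold, demand_target = demand_target,
         horizons = horizons,
         trade_scenario = trade_scenario %||% scenario),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s%s | toggles: %s | demand cap: %s\n",
              x$scenario, if (x$frictionless) " (frictionless)" else "",
              paste(names(x$toggles)[x$toggles], collapse = "+"),
              if (x$demand_capped) format(x$demand_target) else "off"))
  invisible(x)
}

#' Run one projection scenario
#'
#' For each country and horizon: project GDP per capita (accelerated
#' equation below the threshold when the demand toggle is on), map GDP to
#' daily per-capita demand (with the reduced-demand ramp for higher-income
#' countries when configured), look up the population variant, project
#' yield under the configured rule, convert the exogenous net-export dollars
#' to kcal, and solve the accounting identity for cropland area. With
#' `frictionless = TRUE` the global market is additionally cleared at the
#' global average yield. Deterministic given the inputs.
#'
#' @param world A [world_inputs()] object.
#' @param config A [scenario_config()].
#' @return A `projection_result` with elements `country` (per country ×
#'   horizon areas and drivers), `groups` (additions/reductions per income
#'   group), `global` (totals per horizon, with the frictionless total when
#'   requested), and `config`.
#' @export
run_scenario <- function(world, config) {
  stopifnot(inherits(world, "world_inputs"),
            inherits(config, "scenario_config"))
  b <- world$base
  tg <- config$toggles
  out <- vector("list", length(config$horizons))
  for (hi in seq_along(config$horizons)) {
    h <- config$horizons[hi]
    years <- h - world$base_year

    gdp_h <- vapply(seq_len(nrow(b)), function(i) {
      utils::tail(project_gdp(b$gdp_2018[i], world$growth_model, years,
                              accelerated = tg[["demand_boost"]]), 1)
    }, numeric(1))

    if (!is.null(world$demand_paths)) {
      dp <- world$demand_paths
      dp <- dp[dp$horizon == h & dp$scenario == config$scenario, ]
      idx <- match(b$country_id, dp$country_id)
      if (anyNA(idx)) {
        stop("demand_paths missing countries at horizon ", h, ": ",
             paste(b$country_id[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      dem_h <- dp$demand_daily[idx]
    } else {
      dem_h <- project_demand(gdp_h, b$group, world$demand_model)
    }
    if (config$demand_capped) {
      hig <- b$group %in% higher_income_groups()
      dem_h[hig] <- reduced_demand_override(
        b$demand_2018[hig], h, projected_demand = dem_h[hig],
        target = config$demand_target, start_year = world$base_year
      )
    }

    variant <- if (tg[["population_accelerated"]]) "accelerated" else "median"
    pop_h <- population_at(b$country_id, h, variant, world$population)

    cm <- if (h == 2050) b$climate_multiplier_2050 else
      b$climate_multiplier_2100
    ceil <- if (h == 2050) b$ceiling_2050 else b$ceiling_2100
    yld_h <- if (tg[["yield_accelerated"]]) {
      project_yield_accelerated(
        b$yield_2018, b$trend_slope, b$ceiling_2050, b$ceiling_2100, h,
        gdp_pc_base = b$gdp_2018, threshold = config$gdp_threshold,
        climate_multiplier_2050 = b$climate_multiplier_2050,
        climate_multiplier_2100 = b$climate_multiplier_2100,
        base_year = world$base_year
      )
    } else {
      project_yield_bau(b$yield_2018, b$trend_slope, ceil, h,
                        climate_multiplier = cm,
                        base_year = world$base_year)
    }

    te <- world$net_exports
    te <- te[te$scenario == config$trade_scenario & te$horizon == h, ]
    tidx <- match(b$country_id, te$country_id)
    if (anyNA(tidx)) {
      stop("net-export table (", config$trade_scenario, ", ", h,
           ") missing countries: ",
           paste(b$country_id[is.na(tidx)], collapse = ", "), call. = FALSE)
    }
    net_kcal <- usd_to_kcal(te$net_exports_usd[tidx], b$kcal_per_usd,
                            b$group)

    dem_annual <- annual_demand(dem_h)
    ratio <- net_exports_to_ratio(dem_annual, pop_h, net_kcal)
    area_h <- dem_annual * pop_h * ratio / yld_h

    out[[hi]] <- tibble::tibble(
      country_id = b$country_id, group = b$group, horizon = h,
      area_2018 = b$area_2018, area_projected = area_h,
      delta = area_h - b$area_2018,
      demand_daily = dem_h, population = pop_h, yield_kcal = yld_h,
      gdp_pc = gdp_h, net_exports_kcal = net_kcal, ratio = ratio
    )
  }
  country <- dplyr::bind_rows(out)

  glob <- country |>
    dplyr::group_by(horizon) |>
    dplyr::summarise(
      area_2018 = sum(area_2018),
      area_total = sum(area_projected),
      delta_total = sum(delta),
      global_demand = sum(annual_demand(demand_daily) * population),
      .groups = "drop"
    )
  glob$frictionless_area <- NA_real_
  if (config$frictionless) {
    for (i in seq_len(nrow(glob))) {
      cc <- country[country$horizon == glob$horizon[i], ]
      glob$frictionless_area[i] <- frictionless_global_area(
        glob$global_demand[i], cc$yield_kcal, cc$area_2018
      )
    }
  }

  res <- structure(
    list(country = country, global = glob, config = config),
    class = "projection_result"
  )
  res$groups <- aggregate_by_group(res)
  res
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> scenario %s, %d countries\n",
              x$config$scenario, length(unique(x$country$country_id))))
  g <- x$global
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %d: total %.3g ha (delta %+.3g)%s\n", g$horizon[i],
                g$area_total[i], g$delta_total[i],
                if (is.finite(g$frictionless_area[i]))
                  sprintf(", frictionless %.3g ha", g$frictionless_area[i])
                else ""))
  }
  invisible(x)
}

#' Income-group additions and reductions
#'
#' Aggregates country-level cropland deltas within each income group,
#' keeping expansions and retirements separate: `additions` is the sum of
#' positive deltas, `reductions` the sum of negative deltas (reported as a
#' non-positive number), so `additions + reductions` is the group's net
#' change and the sum across groups is the global delta exactly.
#'
#' @param result A `projection_result`, or a country-level tibble with
#'   columns `group, horizon, delta`.
#' @param taxonomy Optional taxonomy tibble remapping `country_id` to
#'   groups; by default the groups already on the result are used. Every
#'   country must be mapped.
#' @return Tibble `group, horizon, additions, reductions, net`.
#' @export
aggregate_by_group <- function(result, taxonomy = NULL) {
  country <- if (inherits(result, "projection_result")) result$country
  else result
  if (!is.null(taxonomy)) {
    taxonomy <- validate_taxonomy(taxonomy)
    idx <- match(country$country_id, taxonomy$country_id)
    if (anyNA(idx)) {
      stop("unmapped country(ies): ",
           paste(unique(country$country_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    country$group <- taxonomy$group[idx]
  }
  stopifnot(all(c("group", "horizon", "delta") %in% names(country)))
  country |>
    dplyr::group_by(group, horizon) |>
    dplyr::summarise(additions = sum(pmax(delta, 0)),
                     reductions = sum(pmin(delta, 0)),
                     net = sum(delta), .groups = "drop")
}

#' Run factor permutations of the accelerated scenario
#'
#' Re-runs the projection with every requested subset of the three
#' accelerated-development factors switched on, holding everything else at
#' business-as-usual. The empty set reproduces the BAU run exactly and the
#' full set reproduces the accelerated scenario exactly; the trade table
#' follows suit (accelerated trade only when all three factors are on).
#'
#' @param world A [world_inputs()] object.
#' @param base_config A [scenario_config()]; its `frictionless` flag,
#'   threshold, and horizons are reused.
#' @param subsets List of character vectors naming the toggles on in each
#'   run; default all 8 subsets of
#'   `{demand_boost, population_accelerated, yield_accelerated}`.
#' @return Tibble `toggle_set, horizon, area_total, frictionless_area` plus
#'   a list-column `result` with the full `projection_result`s.
#' @export
run_permutations <- function(world, base_config = scenario_config("BAU"),
                             subsets = NULL) {
  all_tg <- c("demand_boost", "population_accelerated", "yield_accelerated")
  if (is.null(subsets)) {
    subsets <- unlist(lapply(0:3, function(k)
      utils::combn(all_tg, k, simplify = FALSE)), recursive = FALSE)
  }
  rows <- lapply(subsets, function(on) {
    full <- length(on) == 3
    cfg <- scenario_config(
      scenario = if (full) "accelerated" else "BAU",
      frictionless = base_config$frictionless,
      toggles = stats::setNames(all_tg %in% on, all_tg),
      gdp_threshold = base_config$gdp_threshold,
      demand_target = base_config$demand_target,
      horizons = base_config$horizons,
      trade_scenario = if (full) "accelerated" else "BAU"
    )
    res <- run_scenario(world, cfg)
    g <- res$global
    tibble::tibble(
      toggle_set = paste(sort(on), collapse = "+"),
      n_toggles = length(on),
      horizon = g$horizon, area_total = g$area_total,
      frictionless_area = g$frictionless_area,
      result = rep(list(res), nrow(g))
    )
  })
  dplyr::bind_rows(rows)
}

#' Global totals across scenarios
#'
#' Arranges a set of scenario results into the familiar summary layout:
#' one row per scenario × horizon × trade mode, with the global cropland
#' total and its change from the 2018 base.
#'
#' @param results Named list of `projection_result`s (names used as
#'   scenario labels when present).
#' @return Tibble `scenario, horizon, trade_mode, area_total, delta_vs_2018`.
#' @export
global_summary <- function(results) {
  if (inherits(results, "projection_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    lab <- names(results)[i]
    if (is.null(lab) || !nzchar(lab)) lab <- r$config$scenario
    g <- r$global
    wt <- tibble::tibble(scenario = lab, horizon = g$horizon,
                         trade_mode = "with-trade",
                         area_total = g$area_total,
                         delta_vs_2018 = g$area_total - g$area_2018)
    if (any(is.finite(g$frictionless_area))) {
      fr <- tibble::tibble(scenario = lab, horizon = g$horizon,
                           trade_mode = "frictionless",
                           area_total = g$frictionless_area,
                           delta_vs_2018 = g$frictionless_area - g$area_2018)
      wt <- dplyr::bind_rows(wt, fr)
    }
    wt
  })
  dplyr::bind_rows(rows)
}
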