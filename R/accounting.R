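#' @keywords internal
"_PACKAGE"

## quiets R CMD check notes for NSE column names used throughout
utils::globalVariables(c(
  ".", "country_id", "year", "variable", "value", "unit", "group", "pool",
  "special", "area", "population", "demand_daily", "cereal_yield",
  "export_value", "import_value", "gdp_pc", "suitability_weight",
  "horizon", "scenario", "variant", "net_exports_usd", "kcal_per_usd",
  "delta", "area_projected", "area_2018", "additions", "reductions",
  "rel_value", "base", "weight", "n_years", "min_pop", "yield_kcal",
  "demand_2018", "yield_2018", "trend_slope", "ceiling_2050", "ceiling_2100",
  "climate_multiplier_2050", "climate_multiplier_2100", "net_exports_kcal",
  "gdp_2018", "frictionless", "global_total", "toggle_set", "pop", "demand",
  "yld", "ratio", "prod", "use", "growth", "lambda", "complete",
  "min_pop_ok", "pred1", "n_toggles", "eps", "alpha", "net_kcal_2018",
  "population_2018", "n"
))

#' Days per year used at the daily-to-annual kcal boundary
#'
#' Per-capita crop demand is stored as kcal per person per day everywhere in
#' the package and converted to annual kcal only inside the accounting
#' identity, using a 365-day year.
#'
#' @format A length-one numeric.
#' @export
DAYS_PER_YEAR <- 365

#' Default kilocalories per megagram of generic cereal
#'
#' Used to convert cereal yields in Mg ha^-1 (the unit of the historical
#' panel) to kcal ha^-1 yr^-1 (the unit of the projection engine). The
#' default, 3.56e6 kcal per Mg (3,560 kcal/kg), is a representative energy
#' density for whole cereal grain; per-crop tables can be supplied where the
#' single-cereal simplification is too coarse.
#'
#' @format A length-one numeric, kcal per Mg.
#' @export
KCAL_PER_MG_CEREAL <- 3.56e6

#' Convert a cereal yield from Mg/ha to kcal/ha
#'
#' @param yield_mg_ha Yield in megagrams per hectare (harvested).
#' @param kcal_per_mg Energy density, kcal per Mg. Default
#'   [KCAL_PER_MG_CEREAL].
#' @return Yield in kcal per hectare per year.
#' @export
yield_mg_to_kcal <- function(yield_mg_ha, kcal_per_mg = KCAL_PER_MG_CEREAL) {
  stopifnot(is.numeric(yield_mg_ha), is.numeric(kcal_per_mg), kcal_per_mg > 0)
  yield_mg_ha * kcal_per_mg
}

#' Annualise a daily per-capita kcal demand
#'
#' @param demand_daily kcal per person per day.
#' @return kcal per person per year (`demand_daily * 365`).
#' @export
annual_demand <- function(demand_daily) {
  demand_daily * DAYS_PER_YEAR
}

#' Construct a kcal flow for the accounting identity
#'
#' Bundles the demand-side and supply-side quantities of one country (or any
#' accounting unit) in one year, in consistent kcal units. Production equals
#' yield times cropland area; consumption equals per-capita demand times
#' population times the net-export ratio.
#'
#' @param per_capita_demand Annual per-capita crop demand, kcal person^-1
#'   yr^-1 (use [annual_demand()] to convert a daily value).
#' @param population Persons.
#' @param exports_kcal,imports_kcal Gross crop trade, kcal yr^-1.
#' @param yield_kcal Crop yield, kcal ha^-1 yr^-1.
#' @param area Cropland area, ha (optional; `NA` when the area is the unknown
#'   to be solved for).
#' @return A `kcal_flow` object (named list).
#' @examples
#' fl <- kcal_flow(annual_demand(2500), 1e7, 0, 0, 9.125e6)
#' required_area(fl)
#' @export
kcal_flow <- function(per_capita_demand, population, exports_kcal = 0,
                      imports_kcal = 0, yield_kcal = NA_real_,
                      area = NA_real_) {
  vals <- c(per_capita_demand = per_capita_demand, population = population,
            exports_kcal = exports_kcal, imports_kcal = imports_kcal)
  bad <- names(vals)[!is.finite(vals) | vals < 0]
  if (length(bad)) {
    stop("kcal_flow fields must be finite and non-negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.na(yield_kcal) && yield_kcal < 0) {
    stop("kcal_flow field must be non-negative: yield_kcal", call. = FALSE)
  }
  structure(
    list(per_capita_demand = per_capita_demand, population = population,
         exports_kcal = exports_kcal, imports_kcal = imports_kcal,
         yield_kcal = yield_kcal, area = area),
    class = "kcal_flow"
  )
}

#' @export
print.kcal_flow <- function(x, ...) {
  cat("<kcal_flow>\n")
  cat(sprintf("  demand: %.4g kcal/person/yr  population: %.4g\n",
              x$per_capita_demand, x$population))
  cat(sprintf("  exports: %.4g kcal  imports: %.4g kcal\n",
              x$exports_kcal, x$imports_kcal))
  cat(sprintf("  yield: %.4g kcal/ha  area: %.4g ha\n", x$yield_kcal, x$area))
  invisible(x)
}

#' Net-export ratio of the accounting identity
#'
#' The multiplier that scales a country's domestic crop use up (net exporter)
#' or down (net importer):
#' `1 + (exports - imports) / (per_capita_demand * population)`.
#' The ratio is floored at zero: a country whose imports exceed its entire
#' domestic use cannot require negative cropland, and a warning is raised
#' because such an input is outside the accounting frame.
#'
#' @param per_capita_demand Annual per-capita demand, kcal person^-1 yr^-1;
#'   must be > 0.
#' @param population Persons; must be > 0.
#' @param exports_kcal,imports_kcal Gross trade, kcal yr^-1.
#' @return Dimensionless ratio, >= 0. Equals 1 under autarky or balanced
#'   trade, 2 when net exports equal domestic use.
#' @export
net_export_ratio <- function(per_capita_demand, population,
                             exports_kcal = 0, imports_kcal = 0) {
  if (any(!is.finite(per_capita_demand)) || any(per_capita_demand <= 0)) {
    stop("net_export_ratio: per_capita_demand must be positive", call. = FALSE)
  }
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("net_export_ratio: population must be positive", call. = FALSE)
  }
  ratio <- 1 + (exports_kcal - imports_kcal) / (per_capita_demand * population)
  if (any(ratio < 0)) {
    warning("net-export ratio below 0 (imports exceed total domestic use); ",
            "floored at 0", call. = FALSE)
    ratio <- pmax(ratio, 0)
  }
  ratio
}

#' Cropland area required to satisfy a kcal flow
#'
#' Solves the accounting identity for area:
#' `area = demand * population * ratio / yield`. Homogeneous of degree -1 in
#' yield (doubling yield halves the area), linear in demand, population, and
#' the net-export ratio.
#'
#' @param flow A [kcal_flow()] with a positive `yield_kcal`.
#' @return Required cropland area in hectares.
#' @export
required_area <- function(flow) {
  stopifnot(inherits(flow, "kcal_flow"))
  if (is.na(flow$yield_kcal) || flow$yield_kcal <= 0) {
    stop("required_area: yield_kcal must be positive", call. = FALSE)
  }
  ratio <- net_export_ratio(flow$per_capita_demand, flow$population,
                            flow$exports_kcal, flow$imports_kcal)
  flow$per_capita_demand * flow$population * ratio / flow$yield_kcal
}

#' Crop production from yield and area
#'
#' @param yield_kcal kcal ha^-1 yr^-1, non-negative.
#' @param area ha, non-negative.
#' @return kcal yr^-1. `production(yield, required_area(flow))` round-trips to
#'   `demand * population * ratio` exactly (up to floating point).
#' @export
production <- function(yield_kcal, area) {
  if (any(yield_kcal < 0) || any(area < 0)) {
    stop("production: inputs must be non-negative", call. = FALSE)
  }
  yield_kcal * area
}

#' Split a yield gain into its demand and land-sparing shares
#'
#' Under the log-log driver model the elasticity of cropland area with
#' respect to yield, `beta_yield`, is the fraction of a proportional yield
#' increase that is expressed as cropland reduction; the remainder is
#' absorbed by induced demand (the rebound effect). An estimated elasticity
#' of -0.3 therefore means 30% of a yield gain spares land and 70% meets
#' increased demand.
#'
#' @param beta_yield Yield elasticity of cropland area; interpretable on
#'   \[-1, 0\]. Values outside that range trigger a warning because the
#'   share decomposition no longer sums sensibly.
#' @return A tibble with columns `demand_share` and `land_share` (fractions
#'   summing to 1).
#' @export
yield_passthrough_share <- function(beta_yield) {
  if (any(beta_yield < -1 | beta_yield > 0)) {
    warning("beta_yield outside [-1, 0]; share interpretation breaks down",
            call. = FALSE)
  }
  land <- abs(beta_yield)
  tibble::tibble(demand_share = 1 - land, land_share = land)
}
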