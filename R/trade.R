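#' Convert net exports from USD to kcal
#'
#' Projected net trade arrives in dollars (the trade-model stand-in input);
#' the accounting identity needs kcal. Conversion uses per-country base-year
#' ratios (kcal of net trade per USD of net trade). Countries with a
#' missing ratio fall back to the income-group median ratio, with a
#' warning.
#'
#' @param net_usd Net exports, USD (negative for net importers).
#' @param ratio kcal per USD; positive, possibly `NA`.
#' @param group Income-group label(s), used only for the fallback.
#' @return kcal per year, same sign as `net_usd`.
#' @export
usd_to_kcal <- function(net_usd, ratio, group = NULL) {
  if (any(!is.na(ratio) & ratio <= 0)) {
    stop("conversion ratio must be positive", call. = FALSE)
  }
  if (anyNA(ratio)) {
    if (is.null(group)) {
      stop("missing conversion ratio(s) and no group for fallback",
           call. = FALSE)
    }
    med <- tapply(ratio, group, stats::median, na.rm = TRUE)
    fill <- med[group[is.na(ratio)]]
    if (anyNA(fill)) {
      stop("no group median available for some missing ratios",
           call. = FALSE)
    }
    warning(sum(is.na(ratio)), " missing conversion ratio(s) replaced by ",
            "income-group median", call. = FALSE)
    ratio[is.na(ratio)] <- fill
  }
  net_usd * ratio
}

#' Net-export ratio from a net kcal flow
#'
#' Thin wrapper around [net_export_ratio()] for the projection side, where
#' trade arrives as a single net kcal quantity rather than gross exports
#' and imports: `1 + net_kcal / (demand * population)`, floored at 0.
#'
#' @param per_capita_demand Annual demand, kcal person^-1 yr^-1.
#' @param population Persons.
#' @param net_kcal Net exports, kcal yr^-1 (negative for importers).
#' @return Dimensionless ratio >= 0.
#' @export
net_exports_to_ratio <- function(per_capita_demand, population, net_kcal) {
  net_export_ratio(per_capita_demand, population,
                   exports_kcal = pmax(net_kcal, 0),
                   imports_kcal = pmax(-net_kcal, 0))
}

#' Global cropland under frictionless trade
#'
#' The frictionless counterfactual clears the world market directly:
#' compute base-area production at horizon yields,
#' `P0 = sum(yield_c * area2018_c)`, the implied global average yield
#' `Ybar = P0 / sum(area2018_c)`, and adjust total area by
#' `(global_demand - P0) / Ybar`. Production at the returned area and
#' average yield equals global demand exactly.
#'
#' @param global_demand Global crop demand at the horizon, kcal yr^-1.
#' @param yields Country yields at the horizon, kcal ha^-1; positive.
#' @param areas_2018 Base-year country areas, ha; non-negative with a
#'   positive total.
#' @return Global cropland area, ha.
#' @export
frictionless_global_area <- function(global_demand, yields, areas_2018) {
  stopifnot(length(yields) == length(areas_2018))
  if (any(yields <= 0)) stop("yields must be positive", call. = FALSE)
  if (any(areas_2018 < 0)) stop("areas must be non-negative", call. = FALSE)
  a0 <- sum(areas_2018)
  if (a0 <= 0) stop("total base-year area must be positive", call. = FALSE)
  p0 <- sum(yields * areas_2018)
  ybar <- p0 / a0
  a0 + (global_demand - p0) / ybar
}
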