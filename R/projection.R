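#' GDP-per-capita growth model
#'
#' Annual growth in real per-capita GDP as a convergence-style function of
#' its level: `g(y) = intercept + slope * log(y)` (slope typically negative,
#' so poorer countries grow faster). The accelerated variant applies an
#' alternative, uniformly higher, growth equation whenever current GDP per
#' capita is below the acceleration threshold (default 8,100 in 2010 USD).
#'
#' @param intercept,slope Baseline growth equation (yr^-1, per log-USD).
#' @param acc_intercept,acc_slope Accelerated growth equation; must yield
#'   growth at least the baseline at every GDP below `threshold`.
#' @param threshold Acceleration threshold, 2010 USD per capita.
#' @param bounds Clamp on the annual growth rate, `c(min, max)`; protects
#'   the recursion against divergence, with a message when binding.
#' @return A `growth_model` object.
#' @export
growth_model <- function(intercept = 0.12, slope = -0.011,
                         acc_intercept = intercept + 0.04, acc_slope = slope,
                         threshold = 8100, bounds = c(-0.02, 0.15)) {
  stopifnot(threshold > 0, length(bounds) == 2, bounds[1] < bounds[2])
  gb <- intercept + slope * log(c(1, threshold))
  ga <- acc_intercept + acc_slope * log(c(1, threshold))
  if (any(ga < gb - 1e-12)) {
    stop("accelerated growth must dominate baseline below the threshold",
         call. = FALSE)
  }
  structure(list(intercept = intercept, slope = slope,
                 acc_intercept = acc_intercept, acc_slope = acc_slope,
                 threshold = threshold, bounds = bounds),
            class = "growth_model")
}

#' Estimate a growth model from a historical GDP panel
#'
#' Regresses annual per-capita GDP growth on log GDP per capita:
#' `(y_{t+1} - y_t)/y_t = a + b log(y_t)`. The accelerated variant adds a
#' fixed premium to the intercept.
#'
#' @param records Panel tibble with `country_id, year, gdp_pc`.
#' @param acc_premium Growth premium of the accelerated equation (yr^-1).
#' @param ... Passed to [growth_model()].
#' @return A `growth_model` with estimated `(a, b)`.
#' @export
fit_growth_model <- function(records, acc_premium = 0.04, ...) {
  d <- records |>
    dplyr::arrange(country_id, year) |>
    dplyr::group_by(country_id) |>
    dplyr::mutate(growth = dplyr::lead(gdp_pc) / gdp_pc - 1) |>
    dplyr::ungroup() |>
    dplyr::filter(is.finite(growth), gdp_pc > 0)
  fit <- stats::lm(growth ~ log(gdp_pc), data = d)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  growth_model(intercept = a, slope = b,
               acc_intercept = a + acc_premium, acc_slope = b, ...)
}

#' Project per-capita GDP forward
#'
#' Annual compounding `y_{t+1} = y_t * (1 + g(y_t))` where `g` is the
#' accelerated equation whenever `accelerated = TRUE` and the current GDP is
#' below the model threshold, and the baseline equation otherwise (so a
#' country that crosses the threshold mid-path reverts to baseline growth).
#'
#' @param gdp0 Starting GDP per capita, 2010 USD; > 0.
#' @param model A [growth_model()].
#' @param years Number of annual steps.
#' @param accelerated Apply the accelerated equation below the threshold?
#' @return Numeric GDP path of length `years + 1` (including `gdp0`).
#' @export
project_gdp <- function(gdp0, model, years, accelerated = FALSE) {
  stopifnot(inherits(model, "growth_model"), gdp0 > 0, years >= 0)
  path <- numeric(years + 1)
  path[1] <- gdp0
  clamped <- FALSE
  for (i in seq_len(years)) {
    y <- path[i]
    g <- if (accelerated && y < model$threshold) {
      model$acc_intercept + model$acc_slope * log(y)
    } else {
      model$intercept + model$slope * log(y)
    }
    if (g < model$bounds[1] || g > model$bounds[2]) clamped <- TRUE
    g <- min(max(g, model$bounds[1]), model$bounds[2])
    path[i + 1] <- y * (1 + g)
  }
  if (clamped) {
    message("GDP growth clamped to [", model$bounds[1], ", ",
            model$bounds[2], "] on part of the path")
  }
  path
}

#' Per-capita crop demand model
#'
#' Log-log demand curve per income group:
#' `demand = exp(a_g + b_g * log(gdp_pc))`, clipped to a subsistence floor
#' and a saturation cap (kcal person^-1 day^-1).
#'
#' @param params Tibble or data.frame `group, intercept, elasticity`.
#' @param floor,cap Clip bounds for projected daily demand, kcal/person/day.
#' @param target Reduced-demand endpoint for higher-income countries, kcal
#'   per person per day (default 5,000, the observed 2018 global average).
#' @return A `demand_model` object.
#' @export
demand_model <- function(params, floor = 1500, cap = 20000, target = 5000) {
  stopifnot(all(c("group", "intercept", "elasticity") %in% names(params)),
            floor > 0, cap > floor)
  bad <- setdiff(params$group, income_groups())
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(params = tibble::as_tibble(params), floor = floor,
                 cap = cap, target = target),
            class = "demand_model")
}

#' Estimate the demand model from recent panel years
#'
#' Fits `log(demand_daily) ~ log(gdp_pc)` separately per income group over a
#' recent window (default 2014-2018 analog: the last five panel years).
#'
#' @param records Panel tibble with `demand_daily` and `gdp_pc`.
#' @param taxonomy Taxonomy tibble.
#' @param years Years to use; default the five most recent in the panel.
#' @param ... Passed to [demand_model()].
#' @return A `demand_model` with estimated group curves.
#' @export
fit_demand_model <- function(records, taxonomy, years = NULL, ...) {
  taxonomy <- validate_taxonomy(taxonomy)
  if (is.null(years)) {
    yy <- sort(unique(records$year))
    years <- utils::tail(yy, 5)
  }
  d <- records |>
    dplyr::filter(year %in% years, gdp_pc > 0, demand_daily > 0) |>
    dplyr::select(-dplyr::any_of("group")) |>
    dplyr::inner_join(taxonomy[, c("country_id", "group")], by = "country_id")
  params <- d |>
    dplyr::group_by(group) |>
    dplyr::group_modify(function(g, key) {
      if (length(unique(g$gdp_pc)) < 2) {
        tibble::tibble(intercept = mean(log(g$demand_daily)), elasticity = 0)
      } else {
        cf <- stats::coef(stats::lm(log(demand_daily) ~ log(gdp_pc), data = g))
        tibble::tibble(intercept = unname(cf[1]), elasticity = unname(cf[2]))
      }
    }) |>
    dplyr::ungroup()
  demand_model(params, ...)
}

#' Project per-capita daily crop demand from GDP
#'
#' @param gdp_pc Projected GDP per capita, 2010 USD; > 0.
#' @param group Income-group label(s), recycled against `gdp_pc`.
#' @param model A [demand_model()].
#' @return kcal person^-1 day^-1, clipped to `[floor, cap]`.
#' @export
project_demand <- function(gdp_pc, group, model) {
  stopifnot(inherits(model, "demand_model"), all(gdp_pc > 0))
  idx <- match(group, model$params$group)
  if (anyNA(idx)) {
    stop("unknown income group(s): ",
         paste(unique(group[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  a <- model$params$intercept[idx]
  b <- model$params$elasticity[idx]
  pmin(pmax(exp(a + b * log(gdp_pc)), model$floor), model$cap)
}

#' Reduced-demand override for higher-income countries
#'
#' Linear ramp of daily per-capita demand from its 2018 value down to the
#' target (default 5,000 kcal, the 2018 global average) at 2100. Countries
#' already at or below the target keep their projected demand. Intended for
#' higher-income countries only; the caller applies the group restriction.
#'
#' @param demand_2018 Observed 2018 demand, kcal/person/day.
#' @param horizon_year Year at which demand is needed (2018-2100).
#' @param projected_demand Demand the growth model would give; returned
#'   unchanged for countries already below `target`. Defaults to
#'   `demand_2018`.
#' @param target Endpoint at `end_year`; default 5,000.
#' @param start_year,end_year Ramp anchors; defaults 2018 and 2100.
#' @return kcal person^-1 day^-1.
#' @export
reduced_demand_override <- function(demand_2018, horizon_year,
                                    projected_demand = demand_2018,
                                    target = 5000, start_year = 2018,
                                    end_year = 2100) {
  frac <- (pmin(pmax(horizon_year, start_year), end_year) - start_year) /
    (end_year - start_year)
  ramp <- demand_2018 + (target - demand_2018) * frac
  ifelse(demand_2018 <= target, projected_demand, ramp)
}

#' Look up projected population
#'
#' Population paths are exogenous inputs (UN-median-like and
#' accelerated-development-like variants); this is a checked table lookup.
#'
#' @param country `country_id`(s).
#' @param horizon Horizon year, typically 2050 or 2100.
#' @param variant `"median"` or `"accelerated"`.
#' @param paths Tibble `country_id, horizon, variant, population`.
#' @return Persons, in the order of `country`.
#' @export
population_at <- function(country, horizon, variant, paths) {
  stopifnot(all(c("country_id", "horizon", "variant", "population") %in%
                  names(paths)))
  sub <- paths[paths$horizon == horizon & paths$variant == variant, ]
  idx <- match(country, sub$country_id)
  if (anyNA(idx)) {
    stop("no ", variant, " population path at ", horizon, " for: ",
         paste(unique(country[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  sub$population[idx]
}
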