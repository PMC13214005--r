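#' @importFrom rlang %||%
NULL

#' Specify a synthetic world
#'
#' Parameters of the seeded generator that fabricates a complete study
#' world: a historical country-year panel whose log cropland area follows
#' the two-way fixed-effects driver model with known elasticities, and the
#' projection inputs (population variants, trade tables, ceilings) the
#' scenario engine consumes. Ground truth is known by construction, so
#' every pipeline stage is testable without external data.
#'
#' Group dynamics emulate the stylised historical record: income groups
#' start at different GDP levels and converge slowly ("escaped" groups carry
#' a growth premium), population growth declines with log GDP (demographic
#' transition), yields trend up fast in richer groups and stay nearly flat
#' in the poorest, and per-capita demand follows a log-log curve in GDP.
#' Crop trade closes to zero globally in kcal every year.
#'
#' @param n_per_group Countries per income group (named or scalar).
#' @param years Historical span; default 1961:2018.
#' @param beta True elasticities `(pop, demand, yield, export, import)` of
#'   log cropland area; defaults are the all-countries estimates of the
#'   historical driver model.
#' @param sigma Standard deviation of the i.i.d. log-scale noise.
#' @param fe_sd_country Dispersion of country fixed effects around the
#'   group-level area scale.
#' @param fe_sd_year Innovation s.d. of the year-effect random walk.
#' @param growth_intercept,growth_slope Baseline GDP growth equation
#'   `g = a + b log(gdp)`.
#' @param acc_premium Accelerated-development growth premium below the
#'   threshold.
#' @param gdp_threshold Acceleration threshold, 2010 USD; default 8,100.
#' @param pop_g0,pop_g1 Demographic transition: population growth
#'   `max(0, g0 - g1 log(gdp))`.
#' @param demand_elasticity GDP elasticity of per-capita daily demand.
#' @param kcal_per_mg kcal per Mg of generic cereal.
#' @return A `world_spec` list.
#' @export
world_spec <- function(n_per_group = 4, years = 1961:2018,
                       beta = c(pop = 0.763, demand = 0.351,
                                yield = -0.298, export = 0.065,
                                import = -0.022),
                       sigma = 0.1, fe_sd_country = 0.3, fe_sd_year = 0.02,
                       growth_intercept = 0.10, growth_slope = -0.008,
                       acc_premium = 0.04, gdp_threshold = 8100,
                       pop_g0 = 0.09, pop_g1 = 0.0095,
                       demand_elasticity = 0.30,
                       kcal_per_mg = KCAL_PER_MG_CEREAL) {
  groups <- income_groups()
  if (length(n_per_group) == 1) {
    n_per_group <- stats::setNames(rep(n_per_group, length(groups)), groups)
  }
  stopifnot(all(names(n_per_group) %in% groups), all(n_per_group >= 0),
            sigma >= 0, length(years) >= 2)
  stopifnot(length(beta) == 5)
  names(beta) <- c("pop", "demand", "yield", "export", "import")
  structure(
    list(
      n_per_group = n_per_group, years = years, beta = beta, sigma = sigma,
      fe_sd_country = fe_sd_country, fe_sd_year = fe_sd_year,
      growth_intercept = growth_intercept, growth_slope = growth_slope,
      acc_premium = acc_premium, gdp_threshold = gdp_threshold,
      pop_g0 = pop_g0, pop_g1 = pop_g1,
      demand_elasticity = demand_elasticity, kcal_per_mg = kcal_per_mg,
      ## group baselines at the start of the span
      gdp0 = c("low" = 400, "escaped-low" = 450, "lower-middle" = 800,
               "escaped-lower-middle" = 900, "upper-middle" = 2000,
               "escaped-upper-middle" = 2500, "high" = 8000),
      growth_premium = c("low" = 0, "escaped-low" = 0.02,
                         "lower-middle" = 0, "escaped-lower-middle" = 0.015,
                         "upper-middle" = 0.002,
                         "escaped-upper-middle" = 0.01, "high" = 0),
      demand0 = c("low" = 2000, "escaped-low" = 2100,
                  "lower-middle" = 2300, "escaped-lower-middle" = 2400,
                  "upper-middle" = 4800, "escaped-upper-middle" = 5200,
                  "high" = 7500),
      yield0 = c("low" = 1.0, "escaped-low" = 1.0, "lower-middle" = 1.2,
                 "escaped-lower-middle" = 1.2, "upper-middle" = 1.6,
                 "escaped-upper-middle" = 1.7, "high" = 2.0),
      yield_slope = c("low" = 0.004, "escaped-low" = 0.040,
                      "lower-middle" = 0.015,
                      "escaped-lower-middle" = 0.050,
                      "upper-middle" = 0.050,
                      "escaped-upper-middle" = 0.060, "high" = 0.090),
      ceiling_factor = c("low" = 3.5, "escaped-low" = 3.0,
                         "lower-middle" = 3.0,
                         "escaped-lower-middle" = 2.5,
                         "upper-middle" = 2.0,
                         "escaped-upper-middle" = 1.8, "high" = 1.5),
      area_scale = c("low" = 3e6, "escaped-low" = 3e6,
                     "lower-middle" = 5e6, "escaped-lower-middle" = 5e6,
                     "upper-middle" = 8e6, "escaped-upper-middle" = 8e6,
                     "high" = 1e7)
    ),
    class = "world_spec"
  )
}

#' @keywords internal
country_ids_for <- function(spec) {
  tags <- c("low" = "LIC", "escaped-low" = "ELC", "lower-middle" = "LMC",
            "escaped-lower-middle" = "EMC", "upper-middle" = "UMC",
            "escaped-upper-middle" = "EUC", "high" = "HIC")
  out <- list()
  for (g in names(spec$n_per_group)) {
    n <- spec$n_per_group[[g]]
    if (n > 0) {
      out[[g]] <- tibble::tibble(
        country_id = sprintf("%s%02d", tags[[g]], seq_len(n)), group = g)
    }
  }
  dplyr::bind_rows(out)
}

#' Generate a historical country-year panel with known ground truth
#'
#' Simulates per-country GDP, population, demand, yield, and trade paths
#' under the group dynamics of the spec, then assembles log cropland area
#' from the driver model with the spec's true elasticities, drawn country
#' and year fixed effects, and i.i.d. Gaussian noise. Areas are
#' rescaled by a common per-year factor so that world crop production
#' equals world crop use every year (a closed world); the factor is
#' absorbed by the year fixed effects, leaving the elasticities exactly
#' recoverable.
#'
#' @param spec A [world_spec()].
#' @param seed Integer root seed; fanned out to one sub-seed per country so
#'   partial regeneration is stable.
#' @return List with `panel` (wide tibble; includes `net_exports_kcal`, the
#'   production-minus-use residual), `taxonomy`, `truth` (true beta, fixed
#'   effects), and the `spec`.
#' @export
generate_historical_panel <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "world_spec"))
  if (spec$sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  tax <- country_ids_for(spec)
  yrs <- spec$years
  ny <- length(yrs)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(tax))
  tau <- cumsum(stats::rnorm(ny, 0, spec$fe_sd_year))
  tau <- tau - mean(tau)

  one_country <- function(i) {
    set.seed(sub_seeds[i])
    g <- tax$group[i]
    gdp <- numeric(ny)
    gdp[1] <- spec$gdp0[[g]] * stats::rlnorm(1, 0, 0.25)
    for (t in seq_len(ny - 1)) {
      gr <- spec$growth_intercept + spec$growth_premium[[g]] +
        spec$growth_slope * log(gdp[t])
      gdp[t + 1] <- gdp[t] * (1 + max(min(gr, 0.15), -0.02))
    }
    pop <- numeric(ny)
    pop[1] <- stats::rlnorm(1, log(8e6), 0.8)
    for (t in seq_len(ny - 1)) {
      gp <- max(0, spec$pop_g0 - spec$pop_g1 * log(gdp[t]))
      pop[t + 1] <- pop[t] * (1 + gp)
    }
    a_g <- log(spec$demand0[[g]]) -
      spec$demand_elasticity * log(spec$gdp0[[g]])
    dem <- exp(a_g + spec$demand_elasticity * log(gdp) +
                 stats::rnorm(ny, 0, 0.03))
    yld <- pmax(spec$yield0[[g]] * stats::rlnorm(1, 0, 0.15) +
                  spec$yield_slope[[g]] * (yrs - yrs[1]) +
                  stats::rnorm(ny, 0, 0.02), 0.2)
    ## trade shares follow independent random walks so export and import
    ## values carry independent within-country variation
    exp_share <- exp(log(stats::rlnorm(1, log(0.03), 0.5)) +
                       cumsum(stats::rnorm(ny, 0, 0.08)))
    imp_share <- exp(log(stats::rlnorm(1, log(0.03), 0.5)) +
                       cumsum(stats::rnorm(ny, 0, 0.08)))
    ev <- exp_share * gdp * pop
    iv <- imp_share * gdp * pop
    wsuit <- stats::rlnorm(1, log(spec$area_scale[[g]]), 0.5)
    eps <- stats::rnorm(ny, 0, spec$sigma)
    tibble::tibble(country_id = tax$country_id[i], group = g, year = yrs,
                   gdp_pc = gdp, population = pop, demand_daily = dem,
                   cereal_yield = yld, export_value = ev, import_value = iv,
                   suitability_weight = wsuit, eps = eps)
  }
  panel <- dplyr::bind_rows(lapply(seq_len(nrow(tax)), one_country))

  ## country fixed effect anchors each country's area scale
  set.seed(seed + 1L)
  alpha_tbl <- panel |>
    dplyr::group_by(country_id, group) |>
    dplyr::summarise(pred1 = spec$beta[["pop"]] * log(population[1] / 1e9) +
                       spec$beta[["demand"]] * log(demand_daily[1]) +
                       spec$beta[["yield"]] * log(cereal_yield[1]) +
                       spec$beta[["export"]] * log(export_value[1]) +
                       spec$beta[["import"]] * log(import_value[1]),
                     .groups = "drop")
  alpha_tbl$alpha <- log(spec$area_scale[alpha_tbl$group]) +
    stats::rnorm(nrow(alpha_tbl), 0, spec$fe_sd_country) - alpha_tbl$pred1

  panel <- panel |>
    dplyr::left_join(alpha_tbl[, c("country_id", "alpha")],
                     by = "country_id") |>
    dplyr::mutate(
      area = exp(spec$beta[["pop"]] * log(population / 1e9) +
                   spec$beta[["demand"]] * log(demand_daily) +
                   spec$beta[["yield"]] * log(cereal_yield) +
                   spec$beta[["export"]] * log(export_value) +
                   spec$beta[["import"]] * log(import_value) +
                   alpha + tau[match(year, yrs)] + eps)
    )

  ## close the kcal world each year: rescale areas by a per-year factor so
  ## world production equals world use (the factor is absorbed by the year
  ## fixed effects, so the planted elasticities are untouched)
  panel <- panel |>
    dplyr::group_by(year) |>
    dplyr::mutate(
      lambda = sum(demand_daily * DAYS_PER_YEAR * population) /
        sum(cereal_yield * spec$kcal_per_mg * area),
      area = area * lambda,
      net_exports_kcal = cereal_yield * spec$kcal_per_mg * area -
        demand_daily * DAYS_PER_YEAR * population
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-lambda, -eps, -alpha)

  list(panel = panel, taxonomy = validate_taxonomy(tax),
       truth = list(beta = spec$beta, tau = tau), spec = spec)
}

#' Generate projection inputs consistent with a historical panel
#'
#' Builds the 2018 base table, the median and accelerated population
#' variants (the accelerated variant continues the demographic transition
#' under accelerated GDP growth, so it is never above the median for
#' below-threshold countries and equals it for the rest), yield ceilings at
#' or above current yields, climate multipliers, per-country kcal/USD
#' conversion ratios, and net-export tables for every scenario and horizon
#' that close to zero globally in kcal.
#'
#' @param hist Output of [generate_historical_panel()].
#' @param horizons Projection years; default `c(2050, 2100)`.
#' @param seed Integer seed for the drawn conversion ratios.
#' @param trade_growth Scaling of 2018 net positions per horizon (before
#'   re-closing), named by horizon.
#' @return A [world_inputs()] object.
#' @export
generate_projection_inputs <- function(hist, horizons = c(2050, 2100),
                                       seed = 1L,
                                       trade_growth = c("2050" = 1.1,
                                                        "2100" = 1.25)) {
  spec <- hist$spec
  panel <- hist$panel
  base_year <- max(panel$year)
  last <- panel[panel$year == base_year, ]

  ## yield trends from the recent window of the panel, in kcal/ha
  trend <- panel |>
    dplyr::group_by(country_id) |>
    dplyr::group_modify(function(g, key) {
      ft <- fit_yield_trend(g$year, g$cereal_yield, window = 30)
      tibble::tibble(trend_slope = ft$slope * spec$kcal_per_mg)
    }) |>
    dplyr::ungroup()

  set.seed(seed + 2L)
  base <- last |>
    dplyr::left_join(trend, by = "country_id") |>
    dplyr::transmute(
      country_id, group,
      area_2018 = area, demand_2018 = demand_daily,
      population_2018 = population, gdp_2018 = gdp_pc,
      yield_2018 = cereal_yield * spec$kcal_per_mg,
      trend_slope,
      net_kcal_2018 = net_exports_kcal,
      kcal_per_usd = stats::rlnorm(dplyr::n(), log(2e6), 0.3)
    ) |>
    dplyr::mutate(
      ceiling_2050 = pmax(yield_2018 * spec$ceiling_factor[group],
                          yield_2018 + trend_slope * (2050 - base_year),
                          yield_2018 * 1.05),
      ceiling_2100 = ceiling_2050,
      climate_multiplier_2050 = 1, climate_multiplier_2100 = 1
    )

  ## population variants: continue the demographic transition under
  ## baseline vs accelerated GDP growth
  gmod <- growth_model(intercept = spec$growth_intercept,
                       slope = spec$growth_slope,
                       acc_intercept = spec$growth_intercept +
                         spec$acc_premium,
                       threshold = spec$gdp_threshold)
  project_pop <- function(pop0, gdp0, horizon, accelerated) {
    yrs <- horizon - base_year
    gpath <- project_gdp(gdp0, gmod, yrs, accelerated = accelerated)
    pop <- pop0
    for (t in seq_len(yrs)) {
      gp <- max(0, spec$pop_g0 - spec$pop_g1 * log(gpath[t]))
      pop <- pop * (1 + gp)
    }
    pop
  }
  pop_rows <- list()
  for (h in horizons) {
    for (v in c("median", "accelerated")) {
      pop_rows[[paste(h, v)]] <- tibble::tibble(
        country_id = base$country_id, horizon = h, variant = v,
        population = mapply(project_pop, base$population_2018,
                            base$gdp_2018, h, v == "accelerated")
      )
    }
  }
  population <- dplyr::bind_rows(pop_rows)

  ## demand model estimated from the panel's recent years, as the pipeline
  ## would do on real data (absorbs the generator's level factors)
  dmod <- fit_demand_model(panel, hist$taxonomy)

  ## scenario/horizon net-export tables: scale 2018 positions, nudge the
  ## lower-income half under accelerated development, then re-close
  use_2018 <- base$demand_2018 * DAYS_PER_YEAR * base$population_2018
  share <- use_2018 / sum(use_2018)
  te_rows <- list()
  for (sc in c("BAU", "reduced_demand", "accelerated", "equitable")) {
    for (h in horizons) {
      f <- trade_growth[[as.character(h)]]
      net <- base$net_kcal_2018 * f
      if (sc %in% c("accelerated", "equitable")) {
        lower <- base$group %in% lower_income_groups()
        net[lower] <- net[lower] + 0.2 * abs(net[lower])
      }
      net <- net - share * sum(net)
      te_rows[[paste(sc, h)]] <- tibble::tibble(
        country_id = base$country_id, scenario = sc, horizon = h,
        net_exports_usd = net / base$kcal_per_usd
      )
    }
  }
  net_exports <- dplyr::bind_rows(te_rows)

  world_inputs(base = dplyr::select(base, -net_kcal_2018),
               population = population, net_exports = net_exports,
               demand_model = dmod, growth_model = gmod,
               base_year = base_year)
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: [generate_historical_panel()] then
#' [generate_projection_inputs()] from one root seed.
#'
#' @param spec A [world_spec()]; default `world_spec()`.
#' @param seed Integer root seed.
#' @param horizons Projection years.
#' @return List `panel, taxonomy, truth, world` (a [world_inputs()]).
#' @export
synthetic_world <- function(spec = world_spec(), seed = 1L,
                            horizons = c(2050, 2100)) {
  hist <- generate_historical_panel(spec, seed = seed)
  world <- generate_projection_inputs(hist, horizons = horizons, seed = seed)
  list(panel = hist$panel, taxonomy = hist$taxonomy, truth = hist$truth,
       world = world, spec = spec)
}

#' Freeze a world's projection drivers at their base-year values
#'
#' Returns a copy of the world in which population, demand, yields, and
#' net trade at every horizon and scenario are pinned to their base-year
#' values. Running any scenario on a frozen world must return every
#' country's base-year area exactly (the accounting identity in steady
#' state).
#'
#' @param world A [world_inputs()] object whose base table was built with
#'   consistent base-year net trade (e.g. by the synthetic generator).
#' @param net_kcal_2018 Base-year net exports in kcal per country, in the
#'   order of `world$base$country_id`. Defaults to the residual implied by
#'   the base table (production minus use).
#' @return A frozen `world_inputs`.
#' @export
freeze_world <- function(world, net_kcal_2018 = NULL) {
  stopifnot(inherits(world, "world_inputs"))
  b <- world$base
  if (is.null(net_kcal_2018)) {
    net_kcal_2018 <- b$yield_2018 * b$area_2018 -
      annual_demand(b$demand_2018) * b$population_2018
  }
  horizons <- unique(world$population$horizon)
  scens <- unique(world$net_exports$scenario)
  b$trend_slope <- 0
  b$climate_multiplier_2050 <- 1
  b$climate_multiplier_2100 <- 1
  b$ceiling_2050 <- pmax(b$ceiling_2050, b$yield_2018)
  b$ceiling_2100 <- pmax(b$ceiling_2100, b$yield_2018)
  grid_pop <- expand.grid(horizon = horizons,
                          variant = c("median", "accelerated"),
                          stringsAsFactors = FALSE)
  population <- dplyr::bind_rows(lapply(seq_len(nrow(grid_pop)), function(i)
    tibble::tibble(country_id = b$country_id,
                   horizon = grid_pop$horizon[i],
                   variant = grid_pop$variant[i],
                   population = b$population_2018)))
  grid_te <- expand.grid(scenario = scens, horizon = horizons,
                         stringsAsFactors = FALSE)
  net_exports <- dplyr::bind_rows(lapply(seq_len(nrow(grid_te)), function(i)
    tibble::tibble(country_id = b$country_id,
                   scenario = grid_te$scenario[i],
                   horizon = grid_te$horizon[i],
                   net_exports_usd = net_kcal_2018 / b$kcal_per_usd)))
  demand_paths <- dplyr::bind_rows(lapply(seq_len(nrow(grid_te)), function(i)
    tibble::tibble(country_id = b$country_id,
                   scenario = grid_te$scenario[i],
                   horizon = grid_te$horizon[i],
                   demand_daily = b$demand_2018)))
  world_inputs(base = b, population = population, net_exports = net_exports,
               demand_model = world$demand_model,
               growth_model = world$growth_model,
               demand_paths = demand_paths, base_year = world$base_year)
}

#' A tiny fixed five-country worked example
#'
#' A literal (seed-free) world of five countries with round numbers chosen
#' so the accounting arithmetic can be verified by hand. Net trade sums to
#' zero, so base-area production equals global use and the frictionless
#' clearing leaves the total area unchanged. Ships with the hand-computed
#' expected areas and a literal 3-country, 3-year mini-panel for checking
#' the fixed-effects estimator against the dummy-variable oracle.
#'
#' Hand arithmetic for the expected areas
#' (`area = demand_daily * 365 * pop * ratio / yield`):
#' \itemize{
#'   \item ALP: 2000*365=7.3e5; use 7.3e12; net 0; ratio 1; /7.3e6 = 1.0e6 ha
#'   \item BRV: 2500*365=9.125e5; use 1.825e13; net +1.825e12; ratio 1.1;
#'     /9.125e6 = 2.2e6 ha
#'   \item CED: 3000*365=1.095e6; use 5.475e12; net -1.095e12; ratio 0.8;
#'     /5.475e6 = 8.0e5 ha
#'   \item DOR: 4000*365=1.46e6; use 1.46e14; net 0; ratio 1;
#'     /1.46e7 = 1.0e7 ha
#'   \item EST: 5000*365=1.825e6; use 7.3e13; net -7.3e11; ratio 0.99;
#'     /1.46e7 = 4.95e6 ha
#' }
#' Total 1.895e7 ha; frictionless total equals it (balanced world).
#'
#' @return List with `flows` (tibble of inputs), `expected_area` (named,
#'   ha), `expected_frictionless_total` (ha), and `mini_panel` (literal
#'   panel for the estimator oracle check).
#' @export
worked_example_world <- function() {
  flows <- tibble::tibble(
    country_id = c("ALP", "BRV", "CED", "DOR", "EST"),
    demand_daily = c(2000, 2500, 3000, 4000, 5000),
    population = c(1e7, 2e7, 5e6, 1e8, 4e7),
    net_exports_kcal = c(0, 1.825e12, -1.095e12, 0, -7.3e11),
    yield_kcal = c(7.3e6, 9.125e6, 5.475e6, 1.46e7, 1.46e7)
  )
  expected_area <- c(ALP = 1.0e6, BRV = 2.2e6, CED = 8.0e5, DOR = 1.0e7,
                     EST = 4.95e6)
  mini_panel <- tibble::tibble(
    country_id = rep(c("AAA", "BBB", "CCC"), each = 4),
    year = rep(2001:2004, 3),
    area = c(1.10e6, 1.21e6, 1.35e6, 1.28e6, 2.4e6, 2.3e6, 2.5e6, 2.45e6,
             5.1e5, 5.6e5, 5.3e5, 5.8e5),
    population = c(4.0e6, 4.1e6, 4.3e6, 4.4e6, 9.0e6, 9.2e6, 9.3e6, 9.5e6,
                   2.0e6, 2.1e6, 2.1e6, 2.2e6),
    demand_daily = c(2400, 2450, 2500, 2480, 3000, 3100, 3050, 3150,
                     2100, 2150, 2200, 2180),
    cereal_yield = c(1.5, 1.6, 1.55, 1.62, 2.4, 2.5, 2.6, 2.55,
                     1.1, 1.15, 1.2, 1.18),
    export_value = c(2e7, 2.2e7, 2.1e7, 2.4e7, 8e7, 8.5e7, 9e7, 8.8e7,
                     5e6, 6e6, 5.5e6, 6.2e6),
    import_value = c(3e7, 3.1e7, 3.3e7, 3.2e7, 4e7, 4.2e7, 4.1e7, 4.4e7,
                     9e6, 8e6, 8.5e6, 8.8e6),
    suitability_weight = rep(c(2e6, 6e6, 1e6), each = 4)
  )
  list(flows = flows, expected_area = expected_area,
       expected_frictionless_total = 1.895e7, mini_panel = mini_panel)
}
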