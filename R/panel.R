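#' Country-year panel variables and their units
#'
#' The long-format CSV schema uses these variable names; [read_panel()]
#' pivots them into one row per country-year.
#' @keywords internal
panel_variables <- function() {
  c(area = "ha", population = "persons", demand_daily = "kcal/person/day",
    cereal_yield = "Mg/ha", export_value = "USD2010",
    import_value = "USD2010", gdp_pc = "USD2010/person",
    suitability_weight = "ha")
}

#' Income-group taxonomy labels
#'
#' Seven World-Bank-style income groups (the four 2018 classes plus
#' "escaped" classes for countries that moved up), the three estimation
#' pools they map to, and the higher/lower income split used by the
#' scenario rules.
#'
#' @return `income_groups()`: character vector of the seven group labels.
#' @export
income_groups <- function() {
  c("low", "escaped-low", "lower-middle", "escaped-lower-middle",
    "upper-middle", "escaped-upper-middle", "high")
}

#' @rdname income_groups
#' @return `income_pools()`: named character vector mapping each group to its
#'   estimation pool (`low`, `lower-middle`, `upper`).
#' @export
income_pools <- function() {
  c("low" = "low", "escaped-low" = "low",
    "lower-middle" = "lower-middle", "escaped-lower-middle" = "lower-middle",
    "upper-middle" = "upper", "escaped-upper-middle" = "upper",
    "high" = "upper")
}

#' @rdname income_groups
#' @return `higher_income_groups()` / `lower_income_groups()`: the scenario
#'   split — upper-middle and above count as higher income.
#' @export
higher_income_groups <- function() {
  c("upper-middle", "escaped-upper-middle", "high")
}

#' @rdname income_groups
#' @export
lower_income_groups <- function() {
  c("low", "escaped-low", "lower-middle", "escaped-lower-middle")
}

#' Read a long-format country-year panel
#'
#' Expects a UTF-8 CSV with columns `country_id, year, variable, value,
#' unit` (FAOSTAT-style long export). Validates column presence, numeric
#' cells, duplicate keys, and negative values, reporting row numbers of the
#' offending cells, then pivots to one row per (country_id, year).
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `country_id`, `year`, and one column per
#'   panel variable (see the long schema); attribute `dropped` records rows
#'   excluded for unknown variable names.
#' @export
read_panel <- function(path) {
  ## readr parse issues are re-reported below with row numbers
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    country_id = readr::col_character(),
    year = readr::col_integer(),
    variable = readr::col_character(),
    value = readr::col_double(),
    unit = readr::col_character()
  )))
  required <- c("country_id", "year", "variable", "value")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("panel file missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    stop("non-numeric or malformed cell(s) at row(s): ",
         paste(utils::head(unique(probs$row), 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(raw$value)) {
    stop("missing value cell(s) at row(s): ",
         paste(utils::head(which(is.na(raw$value)), 5), collapse = ", "),
         call. = FALSE)
  }
  neg <- which(raw$value < 0)
  if (length(neg)) {
    stop("negative value(s) at row(s): ",
         paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(raw$country_id, raw$year, raw$variable)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (country_id, year, variable) key(s), first at row ",
         dup[1], ": ", key[dup[1]], call. = FALSE)
  }
  known <- names(panel_variables())
  dropped <- raw[!raw$variable %in% known, , drop = FALSE]
  kept <- raw[raw$variable %in% known, , drop = FALSE]
  wide <- tidyr::pivot_wider(
    dplyr::select(kept, country_id, year, variable, value),
    names_from = variable, values_from = value
  )
  wide <- dplyr::arrange(wide, country_id, year)
  attr(wide, "dropped") <- dropped
  wide
}

#' Write a panel back to the long CSV schema
#'
#' @param records Wide panel tibble as returned by [read_panel()] or
#'   [generate_historical_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(records, path) {
  units <- panel_variables()
  long <- tidyr::pivot_longer(records,
                              cols = dplyr::any_of(names(units)),
                              names_to = "variable", values_to = "value")
  long$unit <- units[long$variable]
  readr::write_csv(dplyr::select(long, country_id, year, variable, value, unit),
                   path)
  invisible(path)
}

#' Read an income-group taxonomy table
#'
#' CSV with columns `country_id, group` and optional `pool`, `special`
#' (flags e.g. the very large countries treated separately). `pool` defaults
#' to the standard three-pool mapping of [income_pools()].
#'
#' @param path Path to the CSV file.
#' @return A tibble `country_id, group, pool, special`.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_csv(path, col_types = readr::cols(
    country_id = readr::col_character(),
    group = readr::col_character(),
    .default = readr::col_character()
  ))
  validate_taxonomy(tax)
}

#' @keywords internal
validate_taxonomy <- function(tax) {
  stopifnot(all(c("country_id", "group") %in% names(tax)))
  bad <- setdiff(unique(tax$group), income_groups())
  if (length(bad)) {
    stop("unknown income group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tax$country_id)) {
    stop("taxonomy assigns a country to more than one group", call. = FALSE)
  }
  if (!"pool" %in% names(tax)) tax$pool <- unname(income_pools()[tax$group])
  if (!"special" %in% names(tax)) tax$special <- NA_character_
  tibble::as_tibble(tax)
}

#' Restrict a panel to the regression sample
#'
#' Applies the estimation-sample rules: keep only countries with a complete
#' series over the requested span, with population at or above the minimum
#' in every year of the span, and not on the exclusion list (countries with
#' border changes, e.g. former-USSR states, supplied as input).
#'
#' The filter is idempotent: applying it twice gives the same sample.
#'
#' @param records Wide panel tibble.
#' @param min_pop Minimum population, persons; default one million.
#' @param span Length-2 integer vector `c(first_year, last_year)`; default
#'   `c(1961, 2016)`.
#' @param exclusions Character vector of `country_id`s to drop.
#' @return The filtered panel (rows restricted to `span`).
#' @export
filter_regression_sample <- function(records, min_pop = 1e6,
                                     span = c(1961, 2016),
                                     exclusions = character()) {
  stopifnot(length(span) == 2, span[1] <= span[2])
  in_span <- dplyr::filter(records, year >= span[1], year <= span[2])
  n_span <- span[2] - span[1] + 1
  core <- c("area", "population", "demand_daily", "cereal_yield",
            "export_value", "import_value")
  core <- intersect(core, names(in_span))
  keep <- in_span |>
    dplyr::group_by(country_id) |>
    dplyr::summarise(
      n_years = dplyr::n(),
      complete = !any(is.na(dplyr::pick(dplyr::all_of(core)))),
      min_pop_ok = all(population >= min_pop),
      .groups = "drop"
    ) |>
    dplyr::filter(n_years == n_span, complete, min_pop_ok) |>
    dplyr::pull(country_id)
  keep <- setdiff(keep, exclusions)
  out <- dplyr::filter(in_span, country_id %in% keep)
  if (nrow(out) == 0) {
    stop("no countries satisfy the regression-sample rules", call. = FALSE)
  }
  out
}

#' Group-level trends relative to a base year
#'
#' For each income group and variable, forms the yearly group aggregate and
#' divides by its base-year value (base year = 1). Aggregation follows the
#' natural weighting of each variable: sums for cropland area and
#' population, a population-weighted mean for per-capita demand, and an
#' area-weighted mean for cereal yield.
#'
#' @param records Wide panel tibble.
#' @param taxonomy Taxonomy tibble (`country_id`, `group`).
#' @param base_year Reference year; every included country must have it.
#' @param weighting `"default"` (weights as above) or `"unweighted"`
#'   (plain means for demand and yield).
#' @return Tidy tibble `group, variable, year, value, rel_value` where
#'   `rel_value` is the aggregate relative to `base_year`.
#' @export
group_trend_report <- function(records, taxonomy, base_year = 1961,
                               weighting = c("default", "unweighted")) {
  weighting <- match.arg(weighting)
  taxonomy <- validate_taxonomy(taxonomy)
  recs <- records |>
    dplyr::select(-dplyr::any_of("group")) |>
    dplyr::inner_join(taxonomy[, c("country_id", "group")], by = "country_id")
  has_base <- recs |>
    dplyr::group_by(country_id) |>
    dplyr::summarise(ok = any(year == base_year), .groups = "drop")
  if (!all(has_base$ok)) {
    stop("base year ", base_year, " missing for: ",
         paste(has_base$country_id[!has_base$ok], collapse = ", "),
         call. = FALSE)
  }
  agg <- recs |>
    dplyr::group_by(group, year) |>
    dplyr::summarise(
      demand_daily = if (weighting == "default") {
        stats::weighted.mean(demand_daily, population)
      } else mean(demand_daily),
      cereal_yield = if (weighting == "default") {
        stats::weighted.mean(cereal_yield, area)
      } else mean(cereal_yield),
      area = sum(area),
      population = sum(population),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c(area, population, demand_daily, cereal_yield),
                        names_to = "variable", values_to = "value")
  agg |>
    dplyr::group_by(group, variable) |>
    dplyr::mutate(rel_value = value / value[year == base_year]) |>
    dplyr::ungroup() |>
    dplyr::arrange(group, variable, year)
}
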