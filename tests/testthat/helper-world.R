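# Shared fixtures and the dummy-variable oracle used across test files.

# A tiny complete wide panel: 3 countries x 3 years, all positive.
tiny_panel <- function() {
  tibble::tibble(
    country_id = rep(c("AAA", "BBB", "CCC"), each = 3),
    year = rep(2001:2003, 3),
    area = c(1e6, 1.1e6, 1.2e6, 2e6, 2.1e6, 2.2e6, 5e5, 5.2e5, 5.4e5),
    population = rep(c(4e6, 9e6, 2e6), each = 3) * rep(c(1, 1.02, 1.04), 3),
    demand_daily = rep(c(2400, 3000, 2100), each = 3),
    cereal_yield = rep(c(1.5, 2.4, 1.1), each = 3),
    export_value = rep(c(2e7, 8e7, 5e6), each = 3),
    import_value = rep(c(3e7, 4e7, 9e6), each = 3),
    gdp_pc = rep(c(1500, 9000, 700), each = 3),
    suitability_weight = rep(c(2e6, 6e6, 1e6), each = 3)
  )
}

tiny_taxonomy <- function() {
  tibble::tibble(country_id = c("AAA", "BBB", "CCC"),
                 group = c("lower-middle", "high", "low"))
}

# Random regression design with country-level weights; optionally drops
# rows to make the panel unbalanced.
random_design <- function(n_c, n_t, seed, drop = 0) {
  set.seed(seed)
  d <- expand.grid(country_id = sprintf("C%02d", seq_len(n_c)),
                   year = 2000 + seq_len(n_t),
                   stringsAsFactors = FALSE)
  if (drop > 0) d <- d[-sample(nrow(d), drop), ]
  for (v in c("log_area", "log_pop_bn", "log_demand", "log_yield",
              "log_export", "log_import")) {
    d[[v]] <- stats::rnorm(nrow(d))
  }
  w <- stats::setNames(stats::runif(n_c, 0.5, 3),
                       sprintf("C%02d", seq_len(n_c)))
  d$weight <- w[d$country_id]
  tibble::as_tibble(d)
}

# Independent oracle: explicit dummy-variable weighted OLS via stats::lm,
# clustered covariance via sandwich::vcovCL.
dummy_fe_oracle <- function(design) {
  fit <- stats::lm(
    log_area ~ log_pop_bn + log_demand + log_yield + log_export +
      log_import + factor(country_id) + factor(year),
    data = design, weights = design$weight
  )
  out <- list(coef = stats::coef(fit)[2:6])
  if (requireNamespace("sandwich", quietly = TRUE)) {
    V <- sandwich::vcovCL(fit, cluster = design$country_id, type = "HC1")
    out$se <- sqrt(diag(V))[2:6]
  }
  out
}

# Small synthetic world reused by scenario tests (cached per session).
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synthetic_world(world_spec(n_per_group = 3,
                                           years = 1990:2018), seed = 101)
    }
    cache
  }
})
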