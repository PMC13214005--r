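test_that("pinball fit on constant data returns the constant", {
  y <- rep(4.2, 25)
  X <- cbind(1, seq_along(y))
  for (tau in c(0.6, 0.9, 0.95)) {
    ft <- pinball_fit(X, y, tau)
    expect_equal(unname(ft$fitted), y, tolerance = 1e-10)
    expect_equal(ft$loss, 0, tolerance = 1e-12)
  }
})

test_that("pinball fit matches a brute-force grid oracle on 10 points", {
  set.seed(17)
  x <- 1:10
  y <- 1 + 0.5 * x + rnorm(10, 0, 0.3)
  tau <- 0.8
  ft <- pinball_fit(cbind(1, x), y, tau)

  # two-stage grid search at 1e-3 final resolution
  grid_loss <- function(a, b) {
    colSums(pinball_loss(outer(y, rep(1, length(a))) -
                           (rep(1, 10) %o% a + x %o% b), tau))
  }
  best <- c(0, 0); best_loss <- Inf
  ctr <- c(1, 0.5); span <- c(2, 1); step <- c(0.05, 0.05)
  for (stage in 1:3) {
    as <- seq(ctr[1] - span[1], ctr[1] + span[1], by = step[1])
    bs <- seq(ctr[2] - span[2], ctr[2] + span[2], by = step[2])
    for (b in bs) {
      ls <- grid_loss(as, rep(b, length(as)))
      i <- which.min(ls)
      if (ls[i] < best_loss) { best_loss <- ls[i]; best <- c(as[i], b) }
    }
    ctr <- best; span <- step * 4; step <- step / 10
  }
  # exact enumeration can only do at least as well as the grid
  expect_lte(ft$loss, best_loss + 1e-9)
  expect_equal(unname(ft$coefficients), best, tolerance = 5e-3)
})

test_that("exceedance fraction tracks 1 - tau", {
  # an exact solution interpolates p points, so the count above the
  # surface is within p of n * (1 - tau)
  n <- 100; tau <- 0.95
  for (s in 1:10) {
    set.seed(s)
    x <- runif(n, 0, 10)
    y <- 2 + 0.3 * x + rexp(n, 1)
    ft <- pinball_fit(cbind(1, x), y, tau)
    expect_lte(abs(ft$exceedance - (1 - tau)), 2 / n)
  }
})

test_that("ceiling models freeze after 2050 and validate inputs", {
  set.seed(4)
  obs <- tibble::tibble(
    unit_id = rep(c("u1", "u2"), each = 30),
    year = rep(1989:2018, 2),
    yield = c(3 + 0.05 * (0:29) + runif(30), 5 + 0.02 * (0:29) + runif(30))
  )
  cm <- fit_ceiling(obs, tau = 0.9)
  expect_s3_class(cm, "ceiling_model")
  expect_equal(nrow(cm$units), 2)
  # linear extrapolation up to the freeze year, constant afterwards
  c2040 <- ceiling_at(cm, "u1", 2040)
  c2050 <- ceiling_at(cm, "u1", 2050)
  c2100 <- ceiling_at(cm, "u1", 2100)
  expect_equal(c2100, c2050)
  expect_false(isTRUE(all.equal(c2040, c2050)))
  expect_error(ceiling_at(cm, "nope", 2050), "unknown unit")

  expect_error(fit_ceiling(obs[1:15, ], tau = 0.9), "observations")
  obs_bad <- obs; obs_bad$year <- 2000  # constant trend column
  expect_error(fit_ceiling(obs_bad, tau = 0.9), "degenerate")
  expect_error(fit_ceiling(obs, tau = 0.4))
})

test_that("business-as-usual projection is trend-capped-at-ceiling", {
  # trend below ceiling: the trend value
  expect_equal(project_yield_bau(2, 0.05, ceiling = 10, horizon = 2050), 3.6)
  # trend above ceiling: the ceiling binds
  expect_equal(project_yield_bau(2, 0.5, ceiling = 10, horizon = 2050), 10)
  # climate multiplier scales the capped value
  expect_equal(project_yield_bau(2, 0.5, 10, 2050,
                                 climate_multiplier = 0.9), 9)
})

test_that("accelerated yield rule follows the stated branches", {
  # slope chosen so the BAU trend value at 2050 is 3
  slope <- 1 / 32
  # max(min(2*2, 8), (3 + 8)/2) = 5.5
  expect_equal(project_yield_accelerated(2, slope, 8, 8, 2050,
                                         gdp_pc_base = 2000), 5.5)
  # ceiling-bound branch: max(min(4, 3.5), (3 + 3.5)/2) = 3.5
  expect_equal(project_yield_accelerated(2, slope, 3.5, 3.5, 2050,
                                         gdp_pc_base = 2000), 3.5)
  # 2100: average of accelerated 2050 and the 2100 ceiling
  expect_equal(project_yield_accelerated(2, slope, 8, 8, 2100,
                                         gdp_pc_base = 2000), 6.75)
  # above the threshold: defers to BAU
  expect_equal(project_yield_accelerated(2, slope, 8, 8, 2050,
                                         gdp_pc_base = 20000),
               project_yield_bau(2, slope, 8, 2050))
})

test_that("accelerated dominates BAU and never exceeds the ceiling", {
  set.seed(12)
  for (i in 1:200) {
    y0 <- runif(1, 0.5, 6)
    slope <- runif(1, -0.01, 0.15)
    ceil <- y0 * runif(1, 1.05, 4)
    cm50 <- runif(1, 0.85, 1)
    cm100 <- runif(1, 0.85, 1)
    for (h in c(2050, 2100)) {
      bau <- project_yield_bau(y0, slope, ceil, h,
                               if (h == 2050) cm50 else cm100)
      acc <- project_yield_accelerated(y0, slope, ceil, ceil, h,
                                       gdp_pc_base = 3000,
                                       climate_multiplier_2050 = cm50,
                                       climate_multiplier_2100 = cm100)
      expect_gte(acc, bau - 1e-12)
      expect_lte(acc, ceil + 1e-12)
    }
  }
})

test_that("country aggregation is a normalised weighted mean", {
  expect_equal(aggregate_country_yield(5, 3), 5)
  expect_equal(aggregate_country_yield(c(4, 6), c(1, 1)), 5)
  # normalisation makes the base year match the national series
  agg_base <- aggregate_country_yield(c(2, 4), c(1, 3),
                                      base_yields = c(2, 4),
                                      national_base = 3.0)
  expect_equal(agg_base, 3.0)
  expect_error(aggregate_country_yield(c(1, 2), c(0, 0)), "positive")
})
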