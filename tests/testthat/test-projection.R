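test_that("GDP projection compounds the growth equation", {
  m <- growth_model(intercept = 0.02, slope = 0, acc_intercept = 0.02)
  p <- project_gdp(1000, m, 10)
  expect_length(p, 11)
  expect_equal(p[11], 1000 * 1.02^10)

  # fixed point g(y*) = 0: a + b log(y*) = 0 -> y* = exp(-a/b)
  m2 <- growth_model(intercept = 0.09, slope = -0.01)
  ystar <- exp(0.09 / 0.01)
  expect_equal(project_gdp(ystar, m2, 5), rep(ystar, 6), tolerance = 1e-12)
})

test_that("acceleration applies only while below the threshold", {
  m <- growth_model(intercept = 0.30, slope = -0.02,
                    acc_intercept = 0.40, threshold = 8100,
                    bounds = c(-0.02, 0.5))
  # independent stepwise recursion over a 5-year toy path
  oracle <- numeric(6); oracle[1] <- 4000
  for (t in 1:5) {
    y <- oracle[t]
    g <- if (y < 8100) 0.40 - 0.02 * log(y) else 0.30 - 0.02 * log(y)
    oracle[t + 1] <- y * (1 + g)
  }
  got <- project_gdp(4000, m, 5, accelerated = TRUE)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(any(got > 8100))  # the toy path does cross

  # dominance: accelerated >= baseline at every horizon when starting below
  base <- project_gdp(4000, m, 5, accelerated = FALSE)
  expect_true(all(got >= base - 1e-9))
  # equal above the threshold
  expect_equal(project_gdp(20000, m, 5, accelerated = TRUE),
               project_gdp(20000, m, 5, accelerated = FALSE))
})

test_that("growth bounds clamp divergent paths with a message", {
  m <- growth_model(intercept = 0.5, slope = 0, acc_intercept = 0.5,
                    bounds = c(-0.02, 0.10))
  expect_message(p <- project_gdp(100, m, 3), "clamped")
  expect_equal(p[4], 100 * 1.10^3)
})

test_that("demand projection follows the group log-log curve", {
  params <- tibble::tibble(group = c("low", "high"),
                           intercept = c(log(2500), 2),
                           elasticity = c(0, 0.3))
  dm <- demand_model(params, floor = 1500, cap = 20000)
  # zero elasticity: constant demand regardless of GDP
  expect_equal(project_demand(c(500, 5e4), c("low", "low"), dm),
               c(2500, 2500))
  # monotone in GDP for non-negative elasticity
  g <- seq(1000, 1e6, length.out = 50)
  d <- project_demand(g, rep("high", 50), dm)
  expect_true(all(diff(d) >= 0))
  # floor and cap respected over a wide GDP range
  expect_true(all(d >= 1500 & d <= 20000))
  expect_error(project_demand(1000, "unknown-group", dm), "unknown")
})

test_that("demand curve estimation recovers known parameters", {
  set.seed(9)
  a <- log(3000) - 0.25 * log(2000)
  gdp <- runif(300, 500, 50000)
  panel <- tibble::tibble(
    country_id = sprintf("C%03d", rep(1:60, each = 5)),
    year = rep(2014:2018, 60),
    gdp_pc = gdp,
    demand_daily = exp(a + 0.25 * log(gdp) + rnorm(300, 0, 0.02))
  )
  tax <- tibble::tibble(country_id = sprintf("C%03d", 1:60), group = "low")
  dm <- fit_demand_model(panel, tax, years = 2014:2018)
  expect_equal(dm$params$elasticity[dm$params$group == "low"], 0.25,
               tolerance = 0.02)
  expect_equal(dm$params$intercept[dm$params$group == "low"], a,
               tolerance = 0.05)
})

test_that("reduced-demand ramp hits the stated anchor points", {
  # higher-income 2018 average ramps to the 5,000 kcal global average
  expect_equal(reduced_demand_override(11500, 2100), 5000)
  expect_equal(reduced_demand_override(11500, 2059), 8250)  # midpoint
  expect_equal(reduced_demand_override(11500, 2018), 11500) # identity at start
  # already below the target: keep the projected demand
  expect_equal(reduced_demand_override(4000, 2100, projected_demand = 4300),
               4300)
  # property: ramp starts at the observed value for any x
  for (x in c(3000, 5000, 7000, 12000)) {
    expect_equal(reduced_demand_override(x, 2018, projected_demand = x), x)
  }
})

test_that("population lookup is exact and lists omissions", {
  paths <- tibble::tibble(
    country_id = rep(c("AAA", "BBB"), each = 4),
    horizon = rep(c(2050, 2050, 2100, 2100), 2),
    variant = rep(c("median", "accelerated"), 4),
    population = c(10, 9, 12, 8, 100, 100, 110, 110)
  )
  expect_equal(population_at("AAA", 2050, "median", paths), 10)
  expect_equal(population_at(c("BBB", "AAA"), 2100, "accelerated", paths),
               c(110, 8))
  expect_error(population_at("ZZZ", 2050, "median", paths), "ZZZ")
})

test_that("generated population variants respect the development logic", {
  sw <- small_world()
  pop <- sw$world$population
  b <- sw$world$base
  med <- population_at(b$country_id, 2100, "median", pop)
  acc <- population_at(b$country_id, 2100, "accelerated", pop)
  lower <- b$group %in% lower_income_groups()
  expect_true(all(acc <= med + 1e-9))
  # high-income countries started above the threshold: variants coincide
  high_gdp <- b$gdp_2018 > 8100
  expect_equal(acc[high_gdp], med[high_gdp], tolerance = 1e-12)
  # and the low-income world is genuinely smaller under acceleration
  expect_lt(sum(acc[lower]), sum(med[lower]))
})
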