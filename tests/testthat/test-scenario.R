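test_that("worked example areas match the recorded hand arithmetic", {
  wx <- worked_example_world()
  fl <- wx$flows
  dem <- annual_demand(fl$demand_daily)
  ratio <- net_exports_to_ratio(dem, fl$population, fl$net_exports_kcal)
  area <- dem * fl$population * ratio / fl$yield_kcal
  expect_equal(unname(area), unname(wx$expected_area[fl$country_id]),
               tolerance = 1e-12)
  # the example world is balanced, so clearing leaves the total unchanged
  fr <- frictionless_global_area(sum(dem * fl$population), fl$yield_kcal,
                                 area)
  expect_equal(fr, wx$expected_frictionless_total, tolerance = 1e-12)
  expect_equal(fr, sum(area), tolerance = 1e-12)
})

test_that("worked example mini-panel estimator agrees with the dummy oracle", {
  wx <- worked_example_world()
  d <- log_transform(wx$mini_panel)
  m <- fit_two_way_fe(d)
  orc <- dummy_fe_oracle(d)
  expect_equal(unname(m$coefficients), unname(orc$coef), tolerance = 1e-8)
})

test_that("a frozen world returns base-year areas at every horizon", {
  sw <- small_world()
  fz <- freeze_world(sw$world)
  res <- run_scenario(fz, scenario_config("BAU"))
  expect_equal(res$country$area_projected, res$country$area_2018,
               tolerance = 1e-12)
  expect_equal(res$global$delta_total, c(0, 0), tolerance = 1e-9)

  # the policy scenarios deliberately move drivers even in a frozen world:
  # the accelerated yield rule can only raise yields, hence shrink areas
  acc <- run_scenario(fz, scenario_config("accelerated"))
  expect_true(all(acc$country$area_projected <=
                    acc$country$area_2018 + 1e-6))
})

test_that("doubling every yield halves every projected area", {
  sw <- small_world()
  w2 <- sw$world
  w2$base$yield_2018 <- 2 * w2$base$yield_2018
  w2$base$trend_slope <- 2 * w2$base$trend_slope
  w2$base$ceiling_2050 <- 2 * w2$base$ceiling_2050
  w2$base$ceiling_2100 <- 2 * w2$base$ceiling_2100
  r1 <- run_scenario(sw$world, scenario_config("BAU"))
  r2 <- run_scenario(w2, scenario_config("BAU"))
  expect_equal(r2$country$area_projected, r1$country$area_projected / 2,
               tolerance = 1e-12)
  expect_equal(r2$global$area_total, r1$global$area_total / 2,
               tolerance = 1e-12)
})

test_that("permutation runs bracket BAU and accelerated exactly", {
  sw <- small_world()
  perms <- run_permutations(sw$world)
  expect_equal(nrow(perms), 8 * 2)

  bau <- run_scenario(sw$world, scenario_config("BAU"))
  acc <- run_scenario(sw$world, scenario_config("accelerated"))
  none <- perms[perms$toggle_set == "", ]
  full <- perms[perms$n_toggles == 3, ]
  expect_identical(none$area_total, bau$global$area_total)
  expect_identical(full$area_total, acc$global$area_total)
  expect_identical(none$result[[1]]$country, bau$country)
  expect_identical(full$result[[1]]$country, acc$country)

  # demand-only acceleration can only increase requirements over BAU
  dem_only <- perms[perms$toggle_set == "demand_boost", ]
  expect_true(all(dem_only$area_total >= none$area_total - 1e-9))
})

test_that("group aggregation separates additions from reductions exactly", {
  ctab <- tibble::tibble(
    country_id = c("a", "b", "c", "d"),
    group = c("low", "low", "high", "high"),
    horizon = 2100,
    delta = c(2, -1, 0, -3)
  )
  g <- aggregate_by_group(ctab)
  expect_equal(g$additions[g$group == "low"], 2)
  expect_equal(g$reductions[g$group == "low"], -1)
  expect_equal(g$net, g$additions + g$reductions)
  expect_equal(sum(g$net), sum(ctab$delta))

  # all-zero deltas
  ctab0 <- ctab; ctab0$delta <- 0
  g0 <- aggregate_by_group(ctab0)
  expect_true(all(g0$additions == 0 & g0$reductions == 0))

  # remapping through a taxonomy must cover every country
  tax <- tibble::tibble(country_id = c("a", "b", "c"), group = "low")
  expect_error(aggregate_by_group(ctab, tax), "unmapped")

  # and the scenario-level identity holds on a real run
  sw <- small_world()
  res <- run_scenario(sw$world, scenario_config("BAU"))
  by_h <- tapply(res$groups$additions + res$groups$reductions,
                 res$groups$horizon, sum)
  expect_equal(as.numeric(by_h), res$global$delta_total, tolerance = 1e-12)
})

test_that("scenario totals are ordered and frictionless needs less land", {
  sw <- small_world()
  runs <- lapply(c(BAU = "BAU", reduced_demand = "reduced_demand",
                   accelerated = "accelerated", equitable = "equitable"),
                 function(sc) suppressWarnings(
                   run_scenario(sw$world,
                                scenario_config(sc, frictionless = TRUE))))
  tot2100 <- vapply(runs, function(r) r$global$area_total[2], numeric(1))
  # equitable combines both levers: smallest requirement at 2100
  expect_lte(tot2100[["equitable"]],
             min(tot2100[["reduced_demand"]], tot2100[["accelerated"]]))
  expect_lte(tot2100[["reduced_demand"]], tot2100[["BAU"]])

  # frictionless clearing never needs more land than the with-trade world
  for (r in runs) {
    expect_true(all(r$global$frictionless_area <=
                      r$global$area_total + 1e-6))
  }

  gs <- global_summary(runs)
  expect_setequal(unique(gs$trade_mode), c("with-trade", "frictionless"))
  expect_equal(nrow(gs), 4 * 2 * 2)
  expect_equal(gs$delta_vs_2018, gs$area_total - sum(sw$world$base$area_2018),
               tolerance = 1e-9)
})

test_that("runs are deterministic and configs compose as documented", {
  sw <- small_world()
  r1 <- suppressWarnings(run_scenario(sw$world, scenario_config("equitable")))
  r2 <- suppressWarnings(run_scenario(sw$world, scenario_config("equitable")))
  expect_identical(r1$country, r2$country)

  cfg <- scenario_config("equitable")
  expect_true(all(cfg$toggles))
  expect_true(cfg$demand_capped)
  cfg_acc <- scenario_config("accelerated")
  expect_true(all(cfg_acc$toggles))
  expect_false(cfg_acc$demand_capped)

  # missing trade table entries are reported by country
  w_bad <- sw$world
  w_bad$net_exports <- w_bad$net_exports[
    w_bad$net_exports$scenario != "equitable", ]
  expect_error(run_scenario(w_bad, cfg), "missing countries|net-export")
})
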