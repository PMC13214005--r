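write_long_csv <- function(panel, path = tempfile(fileext = ".csv")) {
  write_panel(panel, path)
  path
}

test_that("long CSV round-trips through read_panel", {
  p <- tiny_panel()
  got <- read_panel(write_long_csv(p))
  expect_equal(nrow(got), 9)
  expect_setequal(got$country_id, c("AAA", "BBB", "CCC"))
  expect_equal(dplyr::arrange(got, country_id, year)$area, p$area)
})

test_that("malformed panels are rejected with located errors", {
  p <- tiny_panel()
  path <- write_long_csv(p)
  raw <- readr::read_csv(path, show_col_types = FALSE)

  dup <- rbind(raw, raw[1, ])
  f1 <- tempfile(fileext = ".csv"); readr::write_csv(dup, f1)
  expect_error(read_panel(f1), "duplicate")

  neg <- raw; neg$value[4] <- -1
  f2 <- tempfile(fileext = ".csv"); readr::write_csv(neg, f2)
  expect_error(read_panel(f2), "row")

  f3 <- tempfile(fileext = ".csv")
  readr::write_csv(raw[, setdiff(names(raw), "value")], f3)
  expect_error(read_panel(f3), "value")

  txt <- readr::read_lines(path)
  txt[3] <- sub(",[0-9.e+]+,", ",not_a_number,", txt[3])
  f4 <- tempfile(fileext = ".csv"); readr::write_lines(txt, f4)
  expect_error(read_panel(f4), "cell|row")
})

test_that("regression-sample filter applies completeness, size and exclusions", {
  p <- tiny_panel()
  # drop one year from CCC -> incomplete series
  p_inc <- p[!(p$country_id == "CCC" & p$year == 2002), ]
  got <- filter_regression_sample(p_inc, min_pop = 1e6, span = c(2001, 2003))
  expect_setequal(unique(got$country_id), c("AAA", "BBB"))

  # population below threshold in one year
  p_small <- p
  p_small$population[p_small$country_id == "CCC"][2] <- 9e5
  got2 <- filter_regression_sample(p_small, min_pop = 1e6,
                                   span = c(2001, 2003))
  expect_false("CCC" %in% got2$country_id)

  # explicit exclusion list
  got3 <- filter_regression_sample(p, min_pop = 1e6, span = c(2001, 2003),
                                   exclusions = "BBB")
  expect_setequal(unique(got3$country_id), c("AAA", "CCC"))

  # idempotence
  once <- filter_regression_sample(p, span = c(2001, 2003))
  twice <- filter_regression_sample(once, span = c(2001, 2003))
  expect_equal(once, twice)

  expect_error(filter_regression_sample(p, min_pop = 1e12,
                                        span = c(2001, 2003)),
               "no countries")
})

test_that("group trends are relative to the base year", {
  p <- tiny_panel()
  tax <- tiny_taxonomy()
  tr <- group_trend_report(p, tax, base_year = 2001)
  # base year identically 1 for every group/variable
  expect_true(all(abs(tr$rel_value[tr$year == 2001] - 1) < 1e-12))

  # constant panel -> all ones
  pc <- p
  for (v in c("area", "population", "demand_daily", "cereal_yield")) {
    pc[[v]] <- rep(pc[[v]][seq(1, 9, by = 3)], each = 3)
  }
  trc <- group_trend_report(pc, tax, base_year = 2001)
  expect_true(all(abs(trc$rel_value - 1) < 1e-12))

  # single country whose area doubles -> relative series ends at 2
  pd <- p
  pd$area[pd$country_id == "AAA"] <- c(1e6, 1.5e6, 2e6)
  trd <- group_trend_report(pd, tax, base_year = 2001)
  end <- trd$rel_value[trd$group == "lower-middle" & trd$variable == "area" &
                         trd$year == 2003]
  expect_equal(end, 2)

  # two-country group with areas 1 -> 2 and 1 -> 1 aggregates to 1.5
  p2 <- tiny_panel()
  p2$area[p2$country_id == "AAA"] <- c(1e6, 1.5e6, 2e6)
  p2$area[p2$country_id == "CCC"] <- c(1e6, 1e6, 1e6)
  tax2 <- tax; tax2$group <- c("low", "high", "low")
  tr2 <- group_trend_report(p2, tax2, base_year = 2001)
  end2 <- tr2$rel_value[tr2$group == "low" & tr2$variable == "area" &
                          tr2$year == 2003]
  expect_equal(end2, 1.5)

  expect_error(group_trend_report(p, tax, base_year = 1999), "base year")
})

test_that("taxonomy validation enforces one group per country", {
  tax <- tiny_taxonomy()
  expect_silent(got <- read_taxonomy({
    f <- tempfile(fileext = ".csv"); readr::write_csv(tax, f); f
  }))
  expect_true(all(c("pool", "special") %in% names(got)))
  expect_equal(got$pool, unname(income_pools()[tax$group]))

  bad <- tax; bad$group[1] <- "middle-ish"
  expect_error(validate_taxonomy(bad), "unknown income group")
  dup <- rbind(tax, tax[1, ])
  expect_error(validate_taxonomy(dup), "more than one")
})

test_that("income pools partition the seven groups", {
  expect_setequal(names(income_pools()), income_groups())
  expect_setequal(c(higher_income_groups(), lower_income_groups()),
                  income_groups())
})
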