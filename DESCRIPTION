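Package: landreq
Title: Cropland Requirement Accounting, Drivers, and Scenario Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A kilocalorie accounting framework linking crop production,
    per-capita demand, population, trade, yield, and cropland area; a weighted
    two-way fixed-effects panel estimator with country-clustered standard
    errors for the historical drivers of cropland change; quantile-regression
    yield ceilings with constrained trend extrapolation; income-driven demand
    and demographic projection; and a scenario engine that projects country,
    income-group, and global cropland requirements to 2050 and 2100 under
    business-as-usual, reduced-demand, accelerated-development, equitable
    development, and frictionless-trade assumptions. Includes a seeded
    synthetic country-panel generator with known ground truth so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    jsonlite,
    optparse
Config/testthat/edition: 3
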