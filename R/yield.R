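#' Pinball (check) loss
#'
#' Asymmetric absolute loss whose minimiser is the tau-quantile:
#' `u * (tau - 1(u < 0))`.
#'
#' @param u Residuals (observed minus fitted).
#' @param tau Quantile level in (0, 1).
#' @return Loss values, same length as `u`.
#' @export
pinball_loss <- function(u, tau) {
  u * (tau - (u < 0))
}

#' Linear quantile regression by pinball-loss minimisation
#'
#' Fits `y ~ X b` at quantile `tau` by minimising the summed pinball loss.
#' For up to three coefficients the fit is exact: an optimal quantile
#' hyperplane interpolates `p` observations, so all non-singular `p`-point
#' bases are enumerated and the loss-minimising one selected. For wider
#' designs a smoothed-loss quasi-Newton refinement is used (logistic
#' smoothing of the check function with a decreasing bandwidth), started
#' from the least-squares fit.
#'
#' @param X Design matrix (include an intercept column explicitly).
#' @param y Response vector.
#' @param tau Quantile level in (0, 1).
#' @return List with `coefficients`, `fitted`, `loss`, and
#'   `exceedance` (fraction of observations strictly above the surface).
#' @export
pinball_fit <- function(X, y, tau = 0.95) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, tau > 0, tau < 1, n >= p)
  if (qr(X)$rank < p) {
    stop("degenerate covariates: design matrix is rank deficient",
         call. = FALSE)
  }
  intercept_only <- p == 1 && all(X[, 1] == X[1, 1])
  if (intercept_only) {
    b <- stats::quantile(y, tau, type = 1, names = FALSE) / X[1, 1]
    coef <- b
  } else if (p <= 3 && choose(n, p) <= 2e5) {
    combos <- utils::combn(n, p)
    best <- NULL; best_loss <- Inf
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j]
      Xi <- X[idx, , drop = FALSE]
      if (abs(det(Xi)) < 1e-12 * max(abs(Xi), 1)^p) next
      b <- solve(Xi, y[idx])
      l <- sum(pinball_loss(y - X %*% b, tau))
      if (l < best_loss - 1e-12) {
        best_loss <- l; best <- b
      }
    }
    if (is.null(best)) {
      stop("degenerate covariates: no non-singular basis found",
           call. = FALSE)
    }
    coef <- best
  } else {
    coef <- stats::coef(stats::lm.fit(X, y))
    for (h in c(1, 0.1, 0.01, 1e-3, 1e-4) * stats::sd(y)) {
      sm <- function(b) {
        u <- y - X %*% b
        sum(tau * u + h * log1p(exp(-u / h)))
      }
      gr <- function(b) {
        u <- y - X %*% b
        -crossprod(X, tau - 1 / (1 + exp(u / h)))[, 1]
      }
      coef <- stats::optim(coef, sm, gr, method = "BFGS",
                           control = list(maxit = 500))$par
    }
  }
  fitted <- drop(X %*% coef)
  list(coefficients = drop(coef), fitted = fitted,
       loss = sum(pinball_loss(y - fitted, tau)),
       exceedance = mean(y > fitted + 1e-10))
}

#' Fit quantile-regression yield ceilings per unit
#'
#' Estimates an attainable-yield ceiling for each administrative unit (or
#' country) as a high conditional quantile of observed yields on a linear
#' time trend plus optional agro-environmental covariates. The fitted
#' ceiling extrapolates linearly in time but is held constant past the
#' freeze year so that ceilings stay bounded.
#'
#' @param obs Tibble with columns `unit_id, year, yield` plus any covariate
#'   columns named in `covariates`.
#' @param tau Quantile level; default 0.95 (must be in (0.5, 1)).
#' @param covariates Character vector of covariate column names.
#' @param freeze_year Ceilings are constant past this year; default 2050.
#' @param base_year Year at which the trend term is centred; default 2018.
#' @param min_obs Minimum observations per unit; default 20.
#' @return A `ceiling_model`: per-unit coefficients (`intercept`, `trend`,
#'   covariates), `tau`, `freeze_year`, `base_year`, and the per-unit
#'   exceedance fraction (should be about `1 - tau`).
#' @export
fit_ceiling <- function(obs, tau = 0.95, covariates = character(),
                        freeze_year = 2050, base_year = 2018,
                        min_obs = 20) {
  stopifnot(all(c("unit_id", "year", "yield") %in% names(obs)),
            tau > 0.5, tau < 1,
            all(covariates %in% names(obs)))
  fits <- obs |>
    dplyr::group_by(unit_id) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < min_obs) {
        stop("unit ", key$unit_id, " has ", nrow(g), " observations; ",
             min_obs, " required", call. = FALSE)
      }
      X <- cbind(1, g$year - base_year,
                 as.matrix(g[, covariates, drop = FALSE]))
      ft <- pinball_fit(X, g$yield, tau)
      cf <- ft$coefficients
      out <- tibble::tibble(intercept = cf[1], trend = cf[2],
                            exceedance = ft$exceedance, n_obs = nrow(g))
      for (i in seq_along(covariates)) out[[covariates[i]]] <- cf[2 + i]
      out
    }) |>
    dplyr::ungroup()
  structure(list(units = fits, tau = tau, covariates = covariates,
                 freeze_year = freeze_year, base_year = base_year),
            class = "ceiling_model")
}

#' @export
print.ceiling_model <- function(x, ...) {
  cat(sprintf("<ceiling_model> tau = %.2f, %d unit(s), trend frozen past %d\n",
              x$tau, nrow(x$units), x$freeze_year))
  print(as.data.frame(utils::head(x$units, 5)), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Evaluate a yield ceiling at given years
#'
#' @param model A [fit_ceiling()] model.
#' @param unit_id Unit identifier(s).
#' @param year Year(s); the trend is evaluated at `min(year, freeze_year)`.
#' @param newdata Optional tibble of covariate values (one row per query).
#' @return Ceiling yield(s), floored at a small positive value.
#' @export
ceiling_at <- function(model, unit_id, year, newdata = NULL) {
  stopifnot(inherits(model, "ceiling_model"))
  idx <- match(unit_id, model$units$unit_id)
  if (anyNA(idx)) {
    stop("unknown unit(s): ",
         paste(unique(unit_id[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  t_eff <- pmin(year, model$freeze_year) - model$base_year
  val <- model$units$intercept[idx] + model$units$trend[idx] * t_eff
  for (cv in model$covariates) {
    if (is.null(newdata) || !cv %in% names(newdata)) {
      stop("covariate values required for: ", cv, call. = FALSE)
    }
    val <- val + model$units[[cv]][idx] * newdata[[cv]]
  }
  pmax(val, .Machine$double.eps)
}

#' Fit a linear yield trend over a recent window
#'
#' Ordinary least squares of yield on year over the most recent
#' `window` years; the slope extrapolates from the observed base-year
#' yield.
#'
#' @param years,yields Observed series (any consistent yield unit).
#' @param window Number of most recent years to use; default 30.
#' @return List with `slope` (yield units per year) and `base_yield`
#'   (observed yield in the last year used).
#' @export
fit_yield_trend <- function(years, yields, window = 30) {
  stopifnot(length(years) == length(yields), length(years) >= 2)
  o <- order(years)
  years <- years[o]; yields <- yields[o]
  keep <- years > max(years) - window
  yr <- years[keep]; yl <- yields[keep]
  if (length(yr) < 2) stop("need at least 2 years in the trend window",
                           call. = FALSE)
  slope <- unname(stats::coef(stats::lm(yl ~ yr))[2])
  list(slope = slope, base_yield = yl[length(yl)], base_year = max(yr))
}

#' Business-as-usual yield projection
#'
#' Linear extrapolation of the observed yield trend from the base year,
#' capped at the yield ceiling for the same horizon, then scaled by the
#' exogenous climate multiplier (the stand-in for moderate-warming yield
#' impacts) and floored at a small positive value.
#'
#' @param yield_base Observed base-year yield (kcal/ha or Mg/ha,
#'   consistently with `ceiling`).
#' @param trend_slope Yield units per year.
#' @param ceiling Ceiling at the horizon (already frozen past 2050).
#' @param horizon Horizon year.
#' @param climate_multiplier Dimensionless; default 1.
#' @param base_year Default 2018.
#' @return Projected yield at `horizon`.
#' @export
project_yield_bau <- function(yield_base, trend_slope, ceiling, horizon,
                              climate_multiplier = 1, base_year = 2018) {
  raw <- yield_base + trend_slope * (horizon - base_year)
  pmax(pmin(raw, ceiling) * climate_multiplier, .Machine$double.eps)
}

#' Accelerated-development yield projection
#'
#' For countries below the GDP threshold (default 8,100 2010 USD per
#' capita), 2050 yield is the maximum of twice the base-year yield (capped
#' at the ceiling) and the average of the business-as-usual projection and
#' the ceiling; 2100 yield is the average of the accelerated 2050 yield and
#' the 2100 ceiling, guarded from ever falling below the business-as-usual
#' projection. Countries at or above the threshold follow
#' [project_yield_bau()].
#'
#' @param yield_base Observed base-year yield.
#' @param trend_slope Yield units per year.
#' @param ceiling_2050,ceiling_2100 Ceilings at the two horizons (equal when
#'   ceilings freeze in 2050).
#' @param horizon 2050 or 2100.
#' @param gdp_pc_base Base-year GDP per capita, 2010 USD.
#' @param threshold Acceleration threshold; default 8,100.
#' @param climate_multiplier_2050,climate_multiplier_2100 Climate
#'   multipliers used inside the BAU component.
#' @param base_year Default 2018.
#' @return Projected yield at `horizon`; never below the BAU projection and
#'   never above the same-horizon ceiling.
#' @export
project_yield_accelerated <- function(yield_base, trend_slope,
                                      ceiling_2050, ceiling_2100, horizon,
                                      gdp_pc_base, threshold = 8100,
                                      climate_multiplier_2050 = 1,
                                      climate_multiplier_2100 = 1,
                                      base_year = 2018) {
  stopifnot(horizon %in% c(2050, 2100))
  bau_2050 <- project_yield_bau(yield_base, trend_slope, ceiling_2050, 2050,
                                climate_multiplier_2050, base_year)
  acc_2050 <- pmax(pmin(2 * yield_base, ceiling_2050),
                   (bau_2050 + ceiling_2050) / 2)
  if (horizon == 2050) {
    out_acc <- acc_2050
    bau <- bau_2050
  } else {
    bau <- project_yield_bau(yield_base, trend_slope, ceiling_2100, 2100,
                             climate_multiplier_2100, base_year)
    out_acc <- pmax((acc_2050 + ceiling_2100) / 2, bau)
    out_acc <- pmin(out_acc, ceiling_2100)
  }
  ifelse(gdp_pc_base < threshold, out_acc, bau)
}

#' Aggregate unit-level yields to a country yield
#'
#' Harvested-area-weighted mean across administrative units (or crops),
#' optionally rescaled by a national normalisation factor so the aggregated
#' base year matches the national series.
#'
#' @param yields Unit-level yields at the horizon.
#' @param weights Harvested-area weights; must sum to a positive total.
#' @param base_yields Unit-level base-year yields (for normalisation).
#' @param national_base National base-year yield the aggregate must match.
#' @return Country-level yield.
#' @export
aggregate_country_yield <- function(yields, weights, base_yields = NULL,
                                    national_base = NULL) {
  stopifnot(length(yields) == length(weights))
  if (sum(weights) <= 0) stop("total harvested-area weight must be positive",
                              call. = FALSE)
  agg <- stats::weighted.mean(yields, weights)
  if (!is.null(national_base)) {
    stopifnot(!is.null(base_yields), length(base_yields) == length(weights))
    agg <- agg * national_base / stats::weighted.mean(base_yields, weights)
  }
  agg
}
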