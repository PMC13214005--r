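#' Build the log-log design from a panel
#'
#' Transforms the country-year panel into the regression design of the
#' driver model: log cropland area on log population (in billions), log
#' daily per-capita kcal demand, log cereal yield (Mg/ha), and log export
#' and import values (2010 USD), with country and year identifiers and the
#' suitability weight carried along.
#'
#' Export/import values of zero cannot be logged; the `zero_trade` policy is
#' either `"offset"` (add `offset_usd`, default 1 USD, before logging —
#' log(1) = 0 for a true zero) or `"drop"` (exclude the row). Either action
#' is reported with a message. Non-positive values in any other variable
#' drop the row.
#'
#' @param records Wide panel tibble (see [read_panel()]).
#' @param zero_trade Zero-trade policy, `"offset"` (default) or `"drop"`.
#' @param offset_usd Offset added under the `"offset"` policy.
#' @return Tibble with columns `country_id, year, log_area, log_pop_bn,
#'   log_demand, log_yield, log_export, log_import, weight`.
#' @export
log_transform <- function(records, zero_trade = c("offset", "drop"),
                          offset_usd = 1) {
  zero_trade <- match.arg(zero_trade)
  req <- c("country_id", "year", "area", "population", "demand_daily",
           "cereal_yield", "export_value", "import_value",
           "suitability_weight")
  stopifnot(all(req %in% names(records)))
  x <- records
  n0 <- nrow(x)
  zero_tr <- x$export_value <= 0 | x$import_value <= 0
  if (any(zero_tr)) {
    if (zero_trade == "offset") {
      message(sum(zero_tr), " row(s) with zero trade value: offset of ",
              offset_usd, " USD applied before log")
      x$export_value <- ifelse(x$export_value <= 0,
                               x$export_value + offset_usd, x$export_value)
      x$import_value <- ifelse(x$import_value <= 0,
                               x$import_value + offset_usd, x$import_value)
    } else {
      message(sum(zero_tr), " row(s) with zero trade value dropped")
      x <- x[!zero_tr, , drop = FALSE]
    }
  }
  pos <- c("area", "population", "demand_daily", "cereal_yield",
           "export_value", "import_value", "suitability_weight")
  ok <- Reduce(`&`, lapply(pos, function(v) is.finite(x[[v]]) & x[[v]] > 0))
  if (any(!ok)) {
    message(sum(!ok), " row(s) with non-positive values dropped before log")
    x <- x[ok, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("no rows remain after log transform", call. = FALSE)
  tibble::tibble(
    country_id = x$country_id,
    year = x$year,
    log_area = log(x$area),
    log_pop_bn = log(x$population / 1e9),
    log_demand = log(x$demand_daily),
    log_yield = log(x$cereal_yield),
    log_export = log(x$export_value),
    log_import = log(x$import_value),
    weight = x$suitability_weight
  )
}

#' Alternating weighted demeaning over two factors
#'
#' Projects out country and year means (weighted) by alternating
#' projections until convergence; exact for balanced panels in one sweep,
#' iterates for unbalanced ones.
#' @keywords internal
demean_two_way <- function(M, f1, f2, w, tol = 1e-12, max_iter = 1000L) {
  M <- as.matrix(M)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (f in list(f1, f2)) {
      gw <- rowsum(w, f)[, 1]
      gm <- rowsum(M * w, f) / gw
      adj <- gm[match(f, rownames(gm)), , drop = FALSE]
      M <- M - adj
      delta <- max(delta, max(abs(adj)))
    }
    if (delta < tol) break
  }
  M
}

#' Fit the weighted two-way fixed-effects driver model
#'
#' Estimates the log-log cropland driver model with country and year fixed
#' effects by weighted least squares after a two-way within transformation
#' (equivalent to explicit dummy absorption), with cluster-robust standard
#' errors at the country level.
#'
#' The cluster-robust covariance is the standard sandwich with the
#' finite-sample correction `G/(G-1) * (N-1)/(N-k)`, where `G` is the number
#' of clusters (countries), `N` the number of observations and `k` the rank
#' of the full dummy-variable model (slopes plus absorbed country and year
#' effects). The within-R-squared is the share of weighted variance of the
#' doubly demeaned log area explained by the model.
#'
#' @param design Tibble from [log_transform()].
#' @param weights Optional numeric vector overriding `design$weight`
#'   (time-invariant suitability weights; any positive rescaling leaves the
#'   fit unchanged).
#' @param pool Label stored on the model (e.g. `"all"`).
#' @return An object of class `fe_model`: coefficients, clustered SEs,
#'   covariance, fixed effects (`alpha` per country, `tau` per year),
#'   `within_r2`, `n_obs`, `n_countries`, `n_years`, `residuals`.
#' @export
fit_two_way_fe <- function(design, weights = NULL, pool = "all") {
  xvars <- c("log_pop_bn", "log_demand", "log_yield", "log_export",
             "log_import")
  stopifnot(all(c("country_id", "year", "log_area", xvars) %in% names(design)))
  w <- if (is.null(weights)) design$weight else weights
  stopifnot(length(w) == nrow(design), all(w > 0))
  ctry <- as.character(design$country_id)
  yr <- as.character(design$year)
  G <- length(unique(ctry))
  Tn <- length(unique(yr))
  if (G < 2 || Tn < 2) {
    stop("need at least 2 countries and 2 years to identify fixed effects",
         call. = FALSE)
  }
  Y <- design$log_area
  X <- as.matrix(design[, xvars])
  Mt <- demean_two_way(cbind(Y, X), ctry, yr, w)
  y_t <- Mt[, 1]
  X_t <- Mt[, -1, drop = FALSE]

  qx <- qr(sqrt(w) * X_t)
  if (qx$rank < ncol(X_t)) {
    bad <- xvars[qx$pivot[(qx$rank + 1):ncol(X_t)]]
    stop("rank-deficient design after within transformation; ",
         "collinear column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  XtWX <- crossprod(X_t, X_t * w)
  beta <- solve(XtWX, crossprod(X_t, y_t * w))[, 1]
  names(beta) <- xvars
  resid <- y_t - X_t %*% beta
  n <- length(y_t)
  k_full <- length(xvars) + G + Tn - 1L

  ## cluster sandwich: scores w*e*x summed within country
  S <- rowsum(X_t * (w * resid[, 1]), ctry)
  meat <- crossprod(S)
  adj <- (G / (G - 1)) * ((n - 1) / (n - k_full))
  bread <- solve(XtWX)
  vcov_cl <- adj * bread %*% meat %*% bread
  dimnames(vcov_cl) <- list(xvars, xvars)
  se <- sqrt(diag(vcov_cl))

  sst <- sum(w * y_t^2)
  ssr <- sum(w * resid^2)
  within_r2 <- if (sst > 0) 1 - ssr / sst else NA_real_

  ## recover fixed effects from the untransformed residual y - X beta
  r0 <- Y - X %*% beta
  alpha <- rep(0, G); names(alpha) <- sort(unique(ctry))
  tau <- rep(0, Tn); names(tau) <- sort(unique(yr))
  for (it in 1:200) {
    a_new <- rowsum((r0[, 1] - tau[yr]) * w, ctry)[, 1] /
      rowsum(w, ctry)[, 1]
    a_new <- a_new[names(alpha)]
    t_new <- rowsum((r0[, 1] - a_new[ctry]) * w, yr)[, 1] /
      rowsum(w, yr)[, 1]
    t_new <- t_new[names(tau)]
    shift <- stats::weighted.mean(t_new[yr], w)
    t_new <- t_new - shift
    a_new <- a_new + shift
    if (max(abs(a_new - alpha), abs(t_new - tau)) < 1e-12) {
      alpha <- a_new; tau <- t_new; break
    }
    alpha <- a_new; tau <- t_new
  }

  structure(
    list(pool = pool, coefficients = beta, se = se, vcov = vcov_cl,
         alpha = alpha, tau = tau, within_r2 = within_r2,
         n_obs = n, n_countries = G, n_years = Tn,
         residuals = resid[, 1], df_cluster = G - 1L),
    class = "fe_model"
  )
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model> pool: %s | N x T = %d (%d countries, %d years)\n",
              x$pool, x$n_obs, x$n_countries, x$n_years))
  tab <- tidy.fe_model(x)
  print(as.data.frame(tab), row.names = FALSE, digits = 3)
  cat(sprintf("Within R^2: %.3f (SEs clustered by country)\n", x$within_r2))
  invisible(x)
}

#' Tidy a fitted fixed-effects model
#'
#' @param x An `fe_model`.
#' @param ... Unused.
#' @return Tibble `term, estimate, std_error, statistic, p_value, stars`
#'   (t statistics on `G - 1` degrees of freedom, `G` = number of clusters;
#'   stars: `***` p<0.01, `**` p<0.05, `*` p<0.10).
#' @export
tidy.fe_model <- function(x, ...) {
  stat <- x$coefficients / x$se
  p <- 2 * stats::pt(abs(stat), df = x$df_cluster, lower.tail = FALSE)
  stars <- dplyr::case_when(p < 0.01 ~ "***", p < 0.05 ~ "**",
                            p < 0.10 ~ "*", TRUE ~ "")
  tibble::tibble(term = names(x$coefficients), estimate = x$coefficients,
                 std_error = x$se, statistic = stat, p_value = p,
                 stars = stars)
}

#' Fit the driver model for each income pool
#'
#' Fits the all-countries model plus one model per estimation pool
#' (low / lower-middle / upper, each pooling its "escaped" classes). Pools
#' with no countries in the panel are skipped with a warning.
#'
#' @param records Wide panel tibble (already filtered to the estimation
#'   sample; see [filter_regression_sample()]).
#' @param taxonomy Taxonomy tibble with a `pool` column.
#' @param ... Passed to [log_transform()].
#' @return Named list of `fe_model`s: `all` plus one per non-empty pool.
#' @export
fit_by_pool <- function(records, taxonomy, ...) {
  taxonomy <- validate_taxonomy(taxonomy)
  design <- log_transform(records, ...)
  design <- dplyr::inner_join(design,
                              taxonomy[, c("country_id", "pool")],
                              by = "country_id")
  out <- list(all = fit_two_way_fe(design, pool = "all"))
  for (p in c("low", "lower-middle", "upper")) {
    sub <- design[design$pool == p, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("pool '", p, "' is empty; skipped", call. = FALSE)
      next
    }
    out[[p]] <- fit_two_way_fe(sub, pool = p)
  }
  out
}

#' Coefficient table across pools
#'
#' Arranges a list of fitted pool models into the familiar wide layout:
#' one row per regressor with `estimate (SE) stars`, plus observation
#' counts and within-R-squared rows.
#'
#' @param models Named list of `fe_model`s from [fit_by_pool()].
#' @return Tibble with a `term` column and one character column per pool.
#' @export
pool_coef_table <- function(models) {
  cols <- lapply(models, function(m) {
    td <- tidy.fe_model(m)
    c(sprintf("%.3f%s (%.3f)", td$estimate, td$stars, td$std_error),
      format(m$n_obs), sprintf("%.3f", m$within_r2))
  })
  terms <- c(names(models[[1]]$coefficients), "n_obs", "within_r2")
  dplyr::bind_cols(tibble::tibble(term = terms), tibble::as_tibble(cols))
}
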