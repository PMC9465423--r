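# Exposure-response estimation: location-specific Poisson regression of
# daily deaths on a heatwave indicator, meta-analytic pooling to climate
# zones with the Q-test / I^2 model-choice rule, and mapping pooled relative
# risks onto the grid.

new_rr_estimate <- function(level, unit, beta, se, n_sites = 1L,
                            Q = NA_real_, Q_p = NA_real_, I2 = NA_real_,
                            model_used = NA_character_, tau2 = NA_real_) {
  if (se < 0) stop("se must be >= 0", call. = FALSE)
  tibble::tibble(
    level = level, unit = unit, beta = beta, se = se, rr = exp(beta),
    n_sites = as.integer(n_sites), Q = Q, Q_p = Q_p, I2 = I2,
    model_used = model_used, tau2 = tau2
  )
}

#' Fit a location-specific heatwave-mortality relative risk
#'
#' Poisson generalized linear model with log link,
#' `log mu_t = alpha + beta * HW_t + sum(gamma_j x_jt)`; confounders
#' (air-pollution index, relative humidity, seasonality terms, ...) enter as
#' caller-supplied covariate columns. `exp(beta)` is the relative risk of
#' death on heatwave versus non-heatwave days.
#'
#' @param deaths Daily death counts.
#' @param hw Daily 0/1 heatwave indicator, same length.
#' @param covariates Optional data frame of numeric covariates, same length.
#' @param unit Location label carried into the estimate.
#' @return One-row tibble: level, unit, beta, se, rr (and NA meta columns).
#' @export
fit_poisson_rr <- function(deaths, hw, covariates = NULL, unit = "site") {
  if (length(deaths) != length(hw)) {
    stop("deaths and hw must have equal length", call. = FALSE)
  }
  hw <- as.numeric(hw)
  if (length(unique(hw)) < 2L) {
    stop("heatwave indicator is constant: beta is not identifiable", call. = FALSE)
  }
  df <- data.frame(deaths = deaths, hw = hw)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(deaths)) {
      stop("covariates length mismatch", call. = FALSE)
    }
    df <- cbind(df, covariates)
  }
  fit <- stats::glm(deaths ~ ., family = stats::poisson(), data = df,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("Poisson IRLS did not converge", call. = FALSE)
  co <- summary(fit)$coefficients
  new_rr_estimate("location", unit, beta = co["hw", "Estimate"],
                  se = co["hw", "Std. Error"])
}

#' Pool site-level relative risks to a climate zone
#'
#' Inverse-variance meta-analysis with the fixed/random model choice rule:
#' compute Cochran's Q on k-1 degrees of freedom and
#' `I^2 = max(0, (Q - (k-1))/Q) * 100`; when the Q test is significant at
#' `alpha_q` AND I^2 >= 50 percent, pool with DerSimonian-Laird random
#' effects (moment estimator of the between-site variance tau^2), otherwise
#' with fixed effects. A single estimate passes through unchanged.
#'
#' @param estimates Tibble of site estimates (needs `beta`, `se`).
#' @param alpha_q Significance level of the Q test (default 0.05).
#' @param unit Zone label for the pooled estimate.
#' @return One-row tibble with pooled beta, se, rr, Q, Q_p, I2, model_used,
#'   tau2, n_sites.
#' @export
pool_zone <- function(estimates, alpha_q = 0.05, unit = "zone") {
  estimates <- tibble::as_tibble(estimates)
  if (!all(c("beta", "se") %in% names(estimates))) {
    stop("estimates need beta and se columns", call. = FALSE)
  }
  if (any(!is.finite(estimates$beta)) || any(!is.finite(estimates$se))) {
    stop("non-finite estimates", call. = FALSE)
  }
  k <- nrow(estimates)
  if (k == 0L) stop("no estimates to pool", call. = FALSE)
  if (k == 1L) {
    return(new_rr_estimate("zone", unit, estimates$beta, estimates$se,
                           n_sites = 1L, Q = 0, Q_p = 1, I2 = 0,
                           model_used = "fixed", tau2 = 0))
  }
  w <- 1 / estimates$se^2
  if (any(!is.finite(w)) || sum(w) <= 0) stop("all-zero pooling weights", call. = FALSE)
  beta_f <- sum(w * estimates$beta) / sum(w)
  Q <- sum(w * (estimates$beta - beta_f)^2)
  Q_p <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  use_random <- (Q_p < alpha_q) && (I2 >= 50)
  if (use_random) {
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w_r <- 1 / (estimates$se^2 + tau2)
    beta_p <- sum(w_r * estimates$beta) / sum(w_r)
    se_p <- sqrt(1 / sum(w_r))
    model <- "random"
  } else {
    tau2 <- 0
    beta_p <- beta_f
    se_p <- sqrt(1 / sum(w))
    model <- "fixed"
  }
  new_rr_estimate("zone", unit, beta_p, se_p, n_sites = k, Q = Q, Q_p = Q_p,
                  I2 = I2, model_used = model, tau2 = tau2)
}

#' Pool site estimates within each climate zone
#'
#' @param site_estimates Tibble of site-level estimates with a `zone` column.
#' @param alpha_q Q-test significance level.
#' @return Tibble of zone-level pooled estimates, one row per zone.
#' @export
pool_all_zones <- function(site_estimates, alpha_q = 0.05) {
  if (!"zone" %in% names(site_estimates)) {
    stop("site estimates need a zone column", call. = FALSE)
  }
  site_estimates |>
    dplyr::group_by(.data$zone) |>
    dplyr::group_map(~ pool_zone(.x, alpha_q = alpha_q, unit = .y$zone)) |>
    dplyr::bind_rows() |>
    dplyr::rename(zone = "unit")
}

#' Map zone-level relative risks onto grid cells
#'
#' Each grid cell inherits its climate zone's pooled log relative risk and
#' standard error.
#'
#' @param zone_rrs Tibble of zone estimates (zone, beta, se, ...).
#' @param zone_map Tibble (cell_id, zone) assigning every cell to a zone.
#' @return Tibble (cell_id, zone, beta, se, rr).
#' @export
map_rr_to_grid <- function(zone_rrs, zone_map) {
  if (!all(c("cell_id", "zone") %in% names(zone_map))) {
    stop("zone_map needs cell_id and zone", call. = FALSE)
  }
  unmapped <- setdiff(zone_map$zone, zone_rrs$zone)
  if (length(unmapped)) {
    stop(sprintf("no pooled RR for zone(s): %s", paste(unmapped, collapse = ", ")),
         call. = FALSE)
  }
  zone_map |>
    dplyr::select("cell_id", "zone") |>
    dplyr::inner_join(dplyr::select(zone_rrs, "zone", "beta", "se"), by = "zone") |>
    dplyr::mutate(rr = exp(.data$beta))
}
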