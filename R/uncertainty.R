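# Uncertainty propagation: Monte-Carlo sampling of pooled log-RR
# coefficients, pooling of draws across climate-model ensemble members into
# one empirical distribution, and partition of total variability among its
# sources.

# window-mean heatwave "exposure deaths" per zone before the attributable
# fraction is applied: sum over the zone's cells and warm-season months of
# base_deaths * (prop_m / days_m) * HW, averaged over the window years
zone_exposure <- function(dem, cal, window, zone_map) {
  base <- expected_annual_deaths(dem)
  mp <- dem$monthly_prop |>
    dplyr::mutate(daily_frac = .data$proportion / days_in_month(.data$month)) |>
    dplyr::select("month", "daily_frac")
  cal |>
    dplyr::filter(.data$year %in% window) |>
    dplyr::inner_join(mp, by = "month") |>
    dplyr::inner_join(base, by = c("cell_id", "year")) |>
    dplyr::inner_join(dplyr::select(zone_map, "cell_id", "zone"), by = "cell_id") |>
    dplyr::group_by(.data$zone, .data$year) |>
    dplyr::summarise(e = sum(.data$base_deaths * .data$daily_frac * .data$hw_days),
                     .groups = "drop") |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(exposure = sum(.data$e) / length(window), .groups = "drop")
}

#' Monte-Carlo attributable deaths with an empirical confidence interval
#'
#' Draws `n_samples` log-RR coefficient vectors per climate zone from
#' `Normal(beta, se)`, evaluates the window-average national attributable
#' deaths for every draw and every climate-model ensemble member, and pools
#' draws x models into one empirical distribution. The point estimate is
#' the attributable number at the estimated coefficients averaged over the
#' ensemble members; the interval is the stated empirical percentiles of
#' the pooled distribution.
#'
#' @param rr_cells Tibble (cell_id, zone, beta, se) from [map_rr_to_grid()].
#' @param calendars Named list of heatwave calendars, one per climate model.
#' @param dem A [demography()] object.
#' @param window Year range to average over.
#' @param n_samples Number of coefficient draws (default 1000).
#' @param seed Integer seed.
#' @param percentiles Lower/upper empirical percentiles, default 2.5 / 97.5.
#' @param allow_protective Passed to [attributable_fraction()].
#' @return List: `point`, `ci_low`, `ci_high`, `per_model_point` (named),
#'   `draws` (n_samples x n_models matrix of AN values).
#' @export
mc_attributable <- function(rr_cells, calendars, dem, window,
                            n_samples = 1000, seed = 1,
                            percentiles = c(2.5, 97.5),
                            allow_protective = FALSE) {
  if (!length(calendars)) stop("need at least one climate model calendar", call. = FALSE)
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (is.unsorted(percentiles)) stop("percentiles must be ordered", call. = FALSE)
  if (any(rr_cells$se < 0) || any(!is.finite(rr_cells$se))) {
    stop("se must be finite and >= 0", call. = FALSE)
  }
  zones <- rr_cells |>
    dplyr::distinct(.data$zone, .data$beta, .data$se)
  if (anyDuplicated(zones$zone)) {
    stop("beta/se must be constant within a zone", call. = FALSE)
  }
  expo <- purrr::map(calendars, function(cal) {
    e <- zone_exposure(dem, cal, window, rr_cells)
    e$exposure[match(zones$zone, e$zone)]
  })
  an_at <- function(beta_vec, e_vec) {
    af <- suppressWarnings(
      attributable_fraction(exp(beta_vec), allow_protective = allow_protective)
    )
    sum(e_vec * af, na.rm = TRUE)
  }
  per_model_point <- vapply(expo, function(e) an_at(zones$beta, e), numeric(1))
  set.seed(as.integer(seed))
  B <- matrix(stats::rnorm(n_samples * nrow(zones), mean = zones$beta,
                           sd = zones$se),
              nrow = n_samples, byrow = TRUE)
  draws <- vapply(expo, function(e) {
    apply(B, 1, an_at, e_vec = e)
  }, numeric(n_samples))
  draws <- matrix(draws, nrow = n_samples,
                  dimnames = list(NULL, names(calendars)))
  qs <- stats::quantile(as.vector(draws), probs = percentiles / 100,
                        type = 7, names = FALSE)
  list(point = mean(per_model_point), ci_low = qs[1], ci_high = qs[2],
       per_model_point = per_model_point, draws = draws)
}

#' Partition variability in attributable deaths among its sources
#'
#' For each uncertainty source (relative-risk parameters, climate models,
#' population scenarios), evaluates the burden while that source runs over
#' its levels and every other source is pinned to its central level, takes
#' the variance of the results, and normalizes the per-source variances to
#' percentage shares. One-at-a-time evaluation around the central point
#' makes the shares independent of any source ordering by construction.
#'
#' @param an_function Function taking one named argument per source (a
#'   level) and returning a scalar burden.
#' @param source_levels Named list; each element is a list (or vector) of
#'   that source's levels.
#' @param central Named list of central levels; defaults to each source's
#'   middle element.
#' @return Tibble (source, variance, share_pct); shares sum to 100.
#' @export
decompose_uncertainty <- function(an_function, source_levels, central = NULL) {
  if (is.null(names(source_levels)) || any(names(source_levels) == "")) {
    stop("source_levels must be a fully named list", call. = FALSE)
  }
  n_levels <- vapply(source_levels, length, integer(1))
  if (all(n_levels < 2)) {
    stop("at least one source needs >= 2 levels", call. = FALSE)
  }
  if (is.null(central)) {
    central <- purrr::map(source_levels, function(l) l[[ceiling(length(l) / 2)]])
  }
  if (!setequal(names(central), names(source_levels))) {
    stop("central must name every source", call. = FALSE)
  }
  v <- purrr::imap_dbl(source_levels, function(levels, src) {
    if (length(levels) < 2) return(0)
    vals <- vapply(seq_along(levels), function(i) {
      args <- central
      args[[src]] <- levels[[i]]
      do.call(an_function, args)
    }, numeric(1))
    stats::var(vals)
  })
  total <- sum(v)
  if (total <= 0) stop("no variability across any source", call. = FALSE)
  tibble::tibble(source = names(v), variance = unname(v),
                 share_pct = unname(v) / total * 100)
}
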