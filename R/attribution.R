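# Attributable fraction and attributable deaths:
#   AF = (RR - 1) / RR
#   AN_{y,p} = sum_m Pop_{y,p} * (Mort_{y,p} * prop_m / days_m) * HW_{m,y,p} * AF_{y,p}
# with the month sum running over the warm season and, when the demography
# is age-stratified, the Pop * Mort product summed over age groups.

#' Attributable fraction of mortality during heatwave days
#'
#' `AF = (RR - 1) / RR`, the share of deaths on heatwave days attributable
#' to the heatwave. Protective estimates (RR < 1) are floored at zero unless
#' `allow_protective`; the number of floored values is attached as the
#' `n_floored` attribute and signalled with a warning.
#'
#' @param rr Relative risk(s), > 0.
#' @param allow_protective Keep negative AF for RR < 1 instead of flooring.
#' @return Numeric AF, same length as `rr`.
#' @export
attributable_fraction <- function(rr, allow_protective = FALSE) {
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("rr must be finite and > 0", call. = FALSE)
  }
  af <- (rr - 1) / rr
  n_floored <- 0L
  if (!allow_protective && any(af < 0)) {
    n_floored <- sum(af < 0)
    warning(sprintf("%d protective RR value(s) floored to AF = 0", n_floored),
            call. = FALSE)
    af[af < 0] <- 0
  }
  attr(af, "n_floored") <- n_floored
  af
}

#' Attributable deaths per grid cell and year
#'
#' Evaluates the attributable-number equation: for each cell and year, the
#' yearly baseline deaths (population times yearly mortality rate, summed
#' over age groups) are spread into daily rates via the monthly mortality
#' proportions and month lengths, multiplied by the month's heatwave days
#' and by the cell's attributable fraction, and summed over the warm-season
#' months. Mortality rates beyond their freeze year are already frozen
#' inside the demography table.
#'
#' @param dem A [demography()] object.
#' @param cal Heatwave calendar (cell_id, year, month, hw_days).
#' @param af_field Tibble (cell_id, af), e.g. from
#'   `attributable_fraction()` applied to [map_rr_to_grid()] output.
#' @param years Optional year filter; default: years shared by `dem` and `cal`.
#' @return Tibble (cell_id, year, an) — attributable deaths.
#' @export
attributable_deaths <- function(dem, cal, af_field, years = NULL) {
  stopifnot(inherits(dem, "demography"))
  if (!all(c("cell_id", "af") %in% names(af_field))) {
    stop("af_field needs cell_id and af columns", call. = FALSE)
  }
  if (any(af_field$af < 0)) stop("negative attributable fraction", call. = FALSE)
  if (any(cal$hw_days < 0)) stop("negative heatwave-day count", call. = FALSE)
  base <- expected_annual_deaths(dem)
  if (is.null(years)) years <- intersect(unique(base$year), unique(cal$year))
  if (length(years) == 0L) stop("no overlapping years between demography and calendar",
                                call. = FALSE)
  miss_cell <- setdiff(unique(cal$cell_id), af_field$cell_id)
  if (length(miss_cell)) {
    stop(sprintf("af_field missing cell(s): %s",
                 paste(utils::head(miss_cell, 5), collapse = ", ")), call. = FALSE)
  }
  mp <- dem$monthly_prop |>
    dplyr::mutate(daily_frac = .data$proportion / days_in_month(.data$month)) |>
    dplyr::select("month", "daily_frac")
  an <- cal |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::inner_join(mp, by = "month") |>
    dplyr::inner_join(base, by = c("cell_id", "year")) |>
    dplyr::inner_join(dplyr::select(af_field, "cell_id", "af"), by = "cell_id") |>
    dplyr::group_by(.data$cell_id, .data$year) |>
    dplyr::summarise(
      an = sum(.data$base_deaths * .data$daily_frac * .data$hw_days * .data$af),
      .groups = "drop"
    )
  # cells with a calendar but no demography rows would silently vanish
  tidyr::expand_grid(cell_id = unique(cal$cell_id), year = years) |>
    dplyr::left_join(an, by = c("cell_id", "year")) |>
    dplyr::mutate(an = dplyr::coalesce(.data$an, 0))
}

#' Multi-year (decade-window) average of attributable deaths
#'
#' @param res Attribution tibble (cell_id, year, an).
#' @param window Year range, e.g. `1986:2005`; must be fully covered.
#' @param by Aggregation level: per-cell means, or the national total
#'   (sum over cells of the per-cell window means).
#' @param regions Optional tibble (cell_id, region) for regional totals
#'   when `by = "region"`.
#' @return Tibble of window-mean AN at the requested level.
#' @export
decade_average <- function(res, window, by = c("cell", "nation", "region"),
                           regions = NULL) {
  by <- match.arg(by)
  missing_years <- setdiff(window, unique(res$year))
  if (length(missing_years)) {
    stop(sprintf("window year(s) not covered: %s",
                 paste(utils::head(missing_years, 5), collapse = ", ")),
         call. = FALSE)
  }
  cellm <- res |>
    dplyr::filter(.data$year %in% window) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(an = mean(.data$an), .groups = "drop")
  switch(by,
    cell = cellm,
    nation = tibble::tibble(unit = "nation", an = sum(cellm$an)),
    region = {
      if (is.null(regions)) stop("regions table required", call. = FALSE)
      cellm |>
        dplyr::inner_join(regions, by = "cell_id") |>
        dplyr::group_by(.data$region) |>
        dplyr::summarise(an = sum(.data$an), .groups = "drop")
    }
  )
}

#' Percentage change of a future burden relative to baseline
#'
#' `(future - baseline) / baseline * 100`.
#'
#' @param future,baseline Scalars (or equal-length vectors); baseline > 0.
#' @return Percent change.
#' @export
growth_rate <- function(future, baseline) {
  if (any(baseline <= 0)) stop("baseline must be > 0", call. = FALSE)
  (future - baseline) / baseline * 100
}

#' Avoided deaths between two scenarios
#'
#' Elementwise difference of window-average attributable deaths between two
#' scenarios on the same units (cells, regions, or the national total):
#' `res_a - res_b`, e.g. an emission pathway minus the 1.5 degree pathway.
#'
#' @param res_a,res_b Tibbles with an `an` column and identical unit columns
#'   (any columns other than `an`).
#' @return Tibble with the shared unit columns and `an_diff`.
#' @export
scenario_difference <- function(res_a, res_b) {
  keys <- setdiff(names(res_a), "an")
  if (!identical(sort(names(res_a)), sort(names(res_b)))) {
    stop("scenario results have different columns", call. = FALSE)
  }
  j <- dplyr::full_join(res_a, res_b, by = keys, suffix = c("_a", "_b"))
  if (anyNA(j$an_a) || anyNA(j$an_b)) {
    stop("scenario results cover different units", call. = FALSE)
  }
  j |>
    dplyr::mutate(an_diff = .data$an_a - .data$an_b) |>
    dplyr::select(dplyr::all_of(keys), "an_diff")
}
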