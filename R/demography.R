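#' Demography table: population, baseline mortality rates, monthly proportions
#'
#' Bundles the three demographic inputs of the attributable-deaths equation:
#' per-cell age-structured population, yearly baseline mortality rates per
#' age group, and the monthly proportions that convert a yearly rate into a
#' daily rate (`yearly_rate * proportion_m / days_in_month_m`).
#'
#' @param population Tibble (cell_id, year, age_group, population).
#' @param mortality Tibble (year, age_group, yearly_rate) in
#'   deaths/person/year.
#' @param monthly_prop Tibble (month, proportion); proportions over the 12
#'   months must sum to 1.
#' @param scenario Population-scenario label.
#' @return A `demography` object.
#' @export
demography <- function(population, mortality, monthly_prop = monthly_proportions(),
                       scenario = "medium") {
  population <- tibble::as_tibble(population)
  mortality <- tibble::as_tibble(mortality)
  monthly_prop <- tibble::as_tibble(monthly_prop)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(population, c("cell_id", "year", "age_group", "population"), "population")
  need(mortality, c("year", "age_group", "yearly_rate"), "mortality")
  need(monthly_prop, c("month", "proportion"), "monthly_prop")
  if (any(population$population < 0)) stop("negative population", call. = FALSE)
  if (any(mortality$yearly_rate < 0)) stop("negative mortality rate", call. = FALSE)
  if (abs(sum(monthly_prop$proportion) - 1) > 1e-9) {
    stop("monthly proportions must sum to 1", call. = FALSE)
  }
  structure(
    list(population = population, mortality = mortality,
         monthly_prop = monthly_prop, scenario = scenario),
    class = "demography"
  )
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf(
    "<demography> %d cells, years %d-%d, %d age groups, scenario=%s\n",
    dplyr::n_distinct(x$population$cell_id),
    min(x$population$year), max(x$population$year),
    dplyr::n_distinct(x$population$age_group), x$scenario
  ))
  invisible(x)
}

#' Month-length-proportional monthly mortality proportions
#'
#' The default monthly mortality profile: each month's share of annual
#' deaths is proportional to its length in the no-leap calendar, i.e. a
#' uniform daily mortality rate across the year. Real monthly profiles can
#' be supplied to [demography()] instead.
#'
#' @return Tibble (month, proportion) summing to 1.
#' @export
monthly_proportions <- function() {
  tibble::tibble(month = 1:12, proportion = days_in_month(1:12) / 365)
}

#' Collapse a demography to expected annual deaths per cell-year
#'
#' Sums `population * yearly_rate` over age groups: the annual baseline
#' deaths that the attributable-fraction machinery scales.
#'
#' @param dem A [demography()] object.
#' @return Tibble (cell_id, year, base_deaths).
#' @export
expected_annual_deaths <- function(dem) {
  stopifnot(inherits(dem, "demography"))
  dem$population |>
    dplyr::inner_join(dem$mortality, by = c("year", "age_group")) |>
    dplyr::group_by(.data$cell_id, .data$year) |>
    dplyr::summarise(base_deaths = sum(.data$population * .data$yearly_rate),
                     .groups = "drop")
}
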