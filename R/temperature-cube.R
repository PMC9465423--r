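#' Temperature cube: gridded daily maximum temperature
#'
#' A `temperature_cube` holds daily maximum temperature (tasmax, degrees C)
#' for one model run and scenario as a dense day-by-cell matrix plus the
#' no-leap date table and the grid-cell table. It is the raw material for
#' heatwave detection.
#'
#' @param values Numeric matrix, days in rows, grid cells in columns.
#' @param dates Tibble from [noleap_dates()] with one row per matrix row.
#' @param cells Tibble with at least `cell_id`, `lat`, `lon`; one row per
#'   matrix column.
#' @param scenario,model Character labels carried as metadata.
#' @return An object of class `temperature_cube`.
#' @export
temperature_cube <- function(values, dates, cells, scenario = "unknown",
                             model = "unknown") {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop("cube values must be finite numeric", call. = FALSE)
  }
  if (nrow(values) != nrow(dates)) {
    stop("nrow(values) must equal nrow(dates)", call. = FALSE)
  }
  if (ncol(values) != nrow(cells)) {
    stop("ncol(values) must equal nrow(cells)", call. = FALSE)
  }
  if (!all(c("year", "month", "day") %in% names(dates))) {
    stop("dates must have year/month/day columns", call. = FALSE)
  }
  if (!"cell_id" %in% names(cells)) stop("cells must have cell_id", call. = FALSE)
  t_index <- dates$year * 1000L + dates$doy
  if (is.unsorted(t_index, strictly = TRUE)) {
    stop("time axis must be strictly increasing", call. = FALSE)
  }
  colnames(values) <- cells$cell_id
  structure(
    list(values = values, dates = dates, cells = tibble::as_tibble(cells),
         scenario = scenario, model = model, calendar = "noleap"),
    class = "temperature_cube"
  )
}

#' @export
print.temperature_cube <- function(x, ...) {
  cat(sprintf(
    "<temperature_cube> %d days x %d cells (%d-%d), scenario=%s, model=%s\n",
    nrow(x$values), ncol(x$values), min(x$dates$year), max(x$dates$year),
    x$scenario, x$model
  ))
  invisible(x)
}

#' Restrict a temperature cube to a span of years
#'
#' @param cube A [temperature_cube()].
#' @param years Integer vector of years to keep.
#' @return A `temperature_cube` covering only `years`.
#' @export
cube_subset_years <- function(cube, years) {
  stopifnot(inherits(cube, "temperature_cube"))
  keep <- cube$dates$year %in% years
  if (!any(keep)) stop("requested years not present in cube", call. = FALSE)
  temperature_cube(cube$values[keep, , drop = FALSE], cube$dates[keep, ],
                   cube$cells, cube$scenario, cube$model)
}
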