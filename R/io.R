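# File interfaces: CF-style NetCDF for temperature cubes (variable tasmax in
# degC, calendar = "noleap") and CSV schemas for calendars, demography,
# relative risks, and zone maps. CSV readers validate required columns and
# name the missing ones.

#' Write a temperature cube to CF-style NetCDF
#'
#' Dimensions (lon, lat, time), variable `tasmax` in degC, time units
#' `days since <first year>-01-01` with `calendar = "noleap"`. The cube's
#' cells must form a regular lat x lon grid.
#'
#' @param cube A [temperature_cube()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_temperature_nc <- function(cube, path) {
  stopifnot(inherits(cube, "temperature_cube"))
  lats <- sort(unique(cube$cells$lat))
  lons <- sort(unique(cube$cells$lon))
  if (length(lats) * length(lons) != nrow(cube$cells)) {
    stop("cube cells do not form a regular lat x lon grid", call. = FALSE)
  }
  y0 <- cube$dates$year[1]
  dim_t <- ncdf4::ncdim_def("time", sprintf("days since %d-01-01", y0),
                            seq_len(nrow(cube$dates)) - 1L, unlim = TRUE,
                            calendar = "noleap")
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lats)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lons)
  var <- ncdf4::ncvar_def("tasmax", "degC", list(dim_lon, dim_lat, dim_t),
                          missval = NA_real_, prec = "double")
  arr <- array(NA_real_, c(length(lons), length(lats), nrow(cube$dates)))
  i_lon <- match(cube$cells$lon, lons)
  i_lat <- match(cube$cells$lat, lats)
  for (j in seq_len(nrow(cube$cells))) {
    arr[i_lon[j], i_lat[j], ] <- cube$values[, j]
  }
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, var, arr)
  ncdf4::ncatt_put(nc, 0, "scenario", cube$scenario)
  ncdf4::ncatt_put(nc, 0, "model", cube$model)
  invisible(path)
}

#' Read a temperature cube from CF-style NetCDF
#'
#' Inverse of [write_temperature_nc()]. Cell ids are assigned in row-major
#' order (latitude outer, longitude inner), matching [make_grid()].
#'
#' @param path NetCDF file with a `tasmax(lon, lat, time)` variable on a
#'   no-leap calendar.
#' @return A [temperature_cube()].
#' @export
read_temperature_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  lons <- as.vector(ncdf4::ncvar_get(nc, "lon"))
  lats <- as.vector(ncdf4::ncvar_get(nc, "lat"))
  tvals <- as.vector(ncdf4::ncvar_get(nc, "time"))
  cal <- ncdf4::ncatt_get(nc, "time", "calendar")$value
  if (!identical(cal, "noleap")) stop("expected a noleap calendar", call. = FALSE)
  units <- ncdf4::ncatt_get(nc, "time", "units")$value
  y0 <- as.integer(sub("days since (\\d+)-01-01.*", "\\1", units))
  arr <- ncdf4::ncvar_get(nc, "tasmax", collapse_degen = FALSE)
  idx <- as.integer(round(tvals))
  years <- y0 + idx %/% 365L
  dates <- noleap_dates(seq(min(years), max(years)))
  dates <- dates[idx + 1L - (min(years) - y0) * 365L, ]
  cells <- tidyr::expand_grid(lat = lats, lon = lons)
  cells <- tibble::tibble(cell_id = sprintf("c%03d", seq_len(nrow(cells))),
                          lat = cells$lat, lon = cells$lon)
  values <- matrix(NA_real_, length(idx), nrow(cells))
  i_lon <- match(cells$lon, lons)
  i_lat <- match(cells$lat, lats)
  for (j in seq_len(nrow(cells))) values[, j] <- arr[i_lon[j], i_lat[j], ]
  sc <- ncdf4::ncatt_get(nc, 0, "scenario")
  mo <- ncdf4::ncatt_get(nc, 0, "model")
  temperature_cube(values, dates, cells,
                   scenario = if (sc$hasatt) sc$value else "unknown",
                   model = if (mo$hasatt) mo$value else "unknown")
}

#' Read a CSV and validate its schema
#'
#' @param path CSV path.
#' @param required Character vector of required column names.
#' @return Tibble.
#' @export
read_csv_schema <- function(path, required) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Heatwave-calendar CSV round trip
#'
#' Schema: `cell_id, year, month, hw_days`.
#' @param cal Calendar tibble; @param path file path.
#' @return `path` / the calendar tibble.
#' @export
write_calendar_csv <- function(cal, path) {
  readr::write_csv(cal[, c("cell_id", "year", "month", "hw_days")], path)
  invisible(path)
}

#' @rdname write_calendar_csv
#' @export
read_calendar_csv <- function(path) {
  read_csv_schema(path, c("cell_id", "year", "month", "hw_days"))
}

#' Zone-map CSV round trip
#'
#' Schema: `cell_id, zone, province`.
#' @param grid Grid tibble; @param path file path.
#' @return `path` / the zone-map tibble.
#' @export
write_zone_csv <- function(grid, path) {
  readr::write_csv(grid[, c("cell_id", "zone", "province")], path)
  invisible(path)
}

#' @rdname write_zone_csv
#' @export
read_zone_csv <- function(path) {
  read_csv_schema(path, c("cell_id", "zone", "province"))
}

#' Demography CSV round trip
#'
#' Three files: population (`cell_id, year, age_group, population`),
#' mortality (`year, age_group, yearly_rate`), monthly proportions
#' (`month, proportion`).
#'
#' @param dem A [demography()] object.
#' @param dir Directory for the three CSVs.
#' @param prefix Filename prefix.
#' @return The directory / a [demography()] object.
#' @export
write_demography_csv <- function(dem, dir, prefix = "dem") {
  stopifnot(inherits(dem, "demography"))
  readr::write_csv(dem$population, file.path(dir, paste0(prefix, "_population.csv")))
  readr::write_csv(dem$mortality, file.path(dir, paste0(prefix, "_mortality.csv")))
  readr::write_csv(dem$monthly_prop, file.path(dir, paste0(prefix, "_monthly_prop.csv")))
  invisible(dir)
}

#' @rdname write_demography_csv
#' @param scenario Scenario label for the reconstructed object.
#' @export
read_demography_csv <- function(dir, prefix = "dem", scenario = "medium") {
  demography(
    read_csv_schema(file.path(dir, paste0(prefix, "_population.csv")),
                    c("cell_id", "year", "age_group", "population")),
    read_csv_schema(file.path(dir, paste0(prefix, "_mortality.csv")),
                    c("year", "age_group", "yearly_rate")),
    read_csv_schema(file.path(dir, paste0(prefix, "_monthly_prop.csv")),
                    c("month", "proportion")),
    scenario = scenario
  )
}

#' Relative-risk estimate CSV round trip
#'
#' Schema: `level, unit, beta, se, rr, n_sites, Q, Q_p, I2, model_used, tau2`
#' (zone estimates use `zone` in place of `unit`).
#' @param est Estimate tibble; @param path file path.
#' @return `path` / the estimate tibble.
#' @export
write_rr_csv <- function(est, path) {
  readr::write_csv(est, path)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  read_csv_schema(path, c("level", "beta", "se"))
}
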