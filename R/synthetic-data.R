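# Synthetic fixtures with the statistical structure the analysis assumes:
# seasonal-cycle + AR(1) + warming-trend temperature fields, age-structured
# population trajectories with a mid-century peak and an aging trend, and
# Poisson daily death counts with known heatwave relative risks.

#' Define a rectangular half-degree grid with latitude-band climate zones
#'
#' Emulates a gridded study area: `nx` x `ny` cells at `spacing` degrees,
#' split into `n_zones` climate zones by latitude band and into provinces by
#' longitude half within each zone. Annual-mean Tmax (`base_mean`) decreases
#' with latitude so the zones have genuinely different climates.
#'
#' @param nx,ny Grid dimensions (columns of longitude, rows of latitude).
#' @param lat0,lon0 Southwest corner, degrees.
#' @param spacing Cell spacing in degrees.
#' @param n_zones Number of latitude-band climate zones (2-7).
#' @param base_mean_south Annual-mean Tmax at the southern edge, degrees C.
#' @param lapse Decrease in annual-mean Tmax per degree latitude, degrees C.
#' @return Tibble with `cell_id`, `lat`, `lon`, `zone`, `province`,
#'   `base_mean`.
#' @export
make_grid <- function(nx = 10, ny = 10, lat0 = 22, lon0 = 105, spacing = 0.5,
                      n_zones = 4, base_mean_south = 24, lapse = 0.6) {
  if (nx < 1 || ny < 1) stop("grid must have at least one cell", call. = FALSE)
  if (n_zones < 2 || n_zones > 7) stop("n_zones must be in 2..7", call. = FALSE)
  if (n_zones > ny) stop("n_zones cannot exceed ny", call. = FALSE)
  g <- tidyr::expand_grid(
    lat = lat0 + spacing * (seq_len(ny) - 1),
    lon = lon0 + spacing * (seq_len(nx) - 1)
  )
  band <- as.integer(cut(g$lat, breaks = n_zones, labels = FALSE))
  tibble::tibble(
    cell_id = sprintf("c%03d", seq_len(nrow(g))),
    lat = g$lat,
    lon = g$lon,
    zone = sprintf("Z%d", band),
    province = sprintf("P%d%s", band, ifelse(g$lon < stats::median(g$lon), "W", "E")),
    base_mean = base_mean_south - lapse * (g$lat - lat0)
  )
}

#' Specify a climate scenario for the synthetic temperature generator
#'
#' @param name Scenario label (e.g. "ref", "low", "mid", "high").
#' @param years Inclusive year range covered by the run.
#' @param trend Linear warming trend in degrees C per decade.
#' @param sigma AR(1) innovation standard deviation, degrees C.
#' @param rho AR(1) lag-1 autocorrelation, in [0, 1).
#' @param seasonal_amp Amplitude of the annual sinusoid, degrees C (peak
#'   mid-July).
#' @return A `climate_scenario` list.
#' @export
climate_scenario <- function(name, years, trend = 0, sigma = 2, rho = 0.7,
                             seasonal_amp = 10) {
  vals <- c(trend = trend, sigma = sigma, rho = rho, seasonal_amp = seasonal_amp)
  if (any(!is.finite(vals))) stop("scenario parameters must be finite", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  years <- as.integer(years)
  if (length(years) == 0L) stop("years must be non-empty", call. = FALSE)
  structure(
    list(name = name, years = seq(min(years), max(years)), trend = trend,
         sigma = sigma, rho = rho, seasonal_amp = seasonal_amp),
    class = "climate_scenario"
  )
}

#' Generate a gridded daily Tmax cube for a scenario
#'
#' Each cell's series is `base_mean + seasonal sinusoid (peak July 15) +
#' linear trend + AR(1) noise` on the 365-day no-leap calendar. The trend is
#' zero at the first year of the run and accumulates at `trend` degrees C per
#' decade. Output is bit-reproducible for a given seed.
#'
#' @param spec A [climate_scenario()].
#' @param grid Grid tibble from [make_grid()] (needs `cell_id`, `base_mean`).
#' @param seed Integer seed.
#' @param model Climate-model label carried as metadata.
#' @return A [temperature_cube()].
#' @export
generate_temperature <- function(spec, grid, seed, model = "syn1") {
  stopifnot(inherits(spec, "climate_scenario"))
  if (nrow(grid) < 1) stop("grid must have at least one cell", call. = FALSE)
  if (!all(c("cell_id", "base_mean") %in% names(grid))) {
    stop("grid needs cell_id and base_mean columns", call. = FALSE)
  }
  dates <- noleap_dates(spec$years)
  nd <- nrow(dates); nc <- nrow(grid)
  set.seed(as.integer(seed))
  seasonal <- spec$seasonal_amp * cos(2 * pi * (dates$doy - 196) / 365)
  trend <- spec$trend / 10 * (dates$year - spec$years[1] + (dates$doy - 1) / 365)
  noise <- matrix(0, nd, nc)
  if (spec$sigma > 0) {
    innov <- matrix(stats::rnorm(nd * nc, sd = spec$sigma), nd, nc)
    init <- stats::rnorm(nc, sd = spec$sigma / sqrt(1 - spec$rho^2))
    for (j in seq_len(nc)) {
      noise[, j] <- stats::filter(innov[, j], spec$rho, method = "recursive",
                                  init = init[j])
    }
  }
  values <- noise + outer(seasonal + trend, rep(1, nc)) +
    outer(rep(1, nd), grid$base_mean)
  temperature_cube(values, dates, grid, scenario = spec$name, model = model)
}

#' Specify a population scenario
#'
#' @param name Label, e.g. "low", "medium", "high" fertility.
#' @param peak_year Year the total population peaks.
#' @param aging_rate Annual increment in the share of the oldest age group
#'   (fraction per year, taken from the youngest group).
#' @param age_groups Ordered age-band labels, youngest to oldest.
#' @param start_shares Initial age-group shares (sum to 1).
#' @param total0 National total population in the first generated year.
#' @param peak_ratio Peak total relative to `total0`.
#' @param base_rates Named yearly mortality rates per age group
#'   (deaths/person/year).
#' @return A `population_scenario` list.
#' @export
population_scenario <- function(name = "medium", peak_year = 2032,
                                aging_rate = 0.002,
                                age_groups = c("0-64", "65-74", "75+"),
                                start_shares = c(0.80, 0.12, 0.08),
                                total0 = 5e6, peak_ratio = 1.15,
                                base_rates = c("0-64" = 0.003,
                                               "65-74" = 0.020,
                                               "75+" = 0.080)) {
  if (abs(sum(start_shares) - 1) > 1e-9) {
    stop("start_shares must sum to 1", call. = FALSE)
  }
  if (length(start_shares) != length(age_groups)) {
    stop("one start share per age group", call. = FALSE)
  }
  if (any(base_rates < 0)) stop("mortality rates must be >= 0", call. = FALSE)
  if (!setequal(names(base_rates), age_groups)) {
    stop("base_rates must be named by age group", call. = FALSE)
  }
  if (aging_rate < 0) stop("aging_rate must be >= 0", call. = FALSE)
  structure(
    list(name = name, peak_year = as.integer(peak_year),
         aging_rate = aging_rate, age_groups = age_groups,
         start_shares = start_shares, total0 = total0,
         peak_ratio = peak_ratio, base_rates = base_rates[age_groups]),
    class = "population_scenario"
  )
}

#' Generate an age-structured gridded demography table
#'
#' The national total rises smoothly to `peak_year` then declines (Gaussian
#' trajectory in time); the oldest group's share increases linearly at
#' `aging_rate` per year at the expense of the youngest; spatial weights are
#' drawn once per cell and held fixed over time. Yearly mortality rates per
#' age group fluctuate mildly before `freeze_year` and are frozen thereafter
#' at their mean over `freeze_window` (the "2010s" average by default), the
#' standard stable-rates assumption for century-scale projection.
#'
#' @param spec A [population_scenario()].
#' @param grid Grid tibble from [make_grid()].
#' @param years Integer years to generate.
#' @param seed Integer seed.
#' @param freeze_year First year with frozen mortality rates.
#' @param freeze_window Years averaged to form the frozen rate.
#' @return A `demography` object: list with `population` (cell_id, year,
#'   age_group, population), `mortality` (year, age_group, yearly_rate),
#'   `monthly_prop` (month, proportion), and the scenario label.
#' @export
generate_population <- function(spec, grid, years, seed, freeze_year = 2020,
                                freeze_window = 2010:2019) {
  stopifnot(inherits(spec, "population_scenario"))
  years <- sort(as.integer(years))
  set.seed(as.integer(seed))
  nc <- nrow(grid)
  w <- stats::rgamma(nc, shape = 4, rate = 4)
  w <- w / sum(w)
  width <- max(diff(range(c(years, spec$peak_year))), 20) * 0.9
  total <- spec$total0 * spec$peak_ratio *
    exp(-((years - spec$peak_year)^2) / (2 * width^2)) /
    exp(-((years[1] - spec$peak_year)^2) / (2 * width^2))
  k <- length(spec$age_groups)
  elapsed <- years - years[1]
  share_old <- spec$start_shares[k] + spec$aging_rate * elapsed
  if (any(share_old >= 1)) stop("aging_rate drives the oldest share past 1", call. = FALSE)
  share_young <- spec$start_shares[1] - spec$aging_rate * elapsed
  if (any(share_young <= 0)) stop("aging_rate exhausts the youngest group", call. = FALSE)
  shares <- matrix(rep(spec$start_shares, each = length(years)),
                   nrow = length(years))
  shares[, 1] <- share_young
  shares[, k] <- share_old
  colnames(shares) <- spec$age_groups

  pop <- tidyr::expand_grid(cell_id = grid$cell_id, year = years) |>
    dplyr::left_join(tibble::tibble(cell_id = grid$cell_id, w = w), by = "cell_id") |>
    dplyr::left_join(tibble::tibble(year = years, total = total), by = "year")
  pop <- tidyr::expand_grid(pop, age_group = spec$age_groups)
  sh <- tibble::tibble(
    year = rep(years, times = k),
    age_group = rep(spec$age_groups, each = length(years)),
    share = as.vector(shares)
  )
  pop <- pop |>
    dplyr::left_join(sh, by = c("year", "age_group")) |>
    dplyr::mutate(population = .data$w * .data$total * .data$share) |>
    dplyr::select("cell_id", "year", "age_group", "population")

  # mildly fluctuating historical rates, frozen at the freeze-window mean
  rate_years <- years
  mort <- tidyr::expand_grid(year = rate_years, age_group = spec$age_groups) |>
    dplyr::left_join(tibble::tibble(age_group = spec$age_groups,
                                    base = unname(spec$base_rates)),
                     by = "age_group")
  wiggle <- stats::rnorm(nrow(mort), sd = 0.01)
  mort$yearly_rate <- mort$base * (1 + wiggle)
  frozen <- mort |>
    dplyr::filter(.data$year %in% freeze_window) |>
    dplyr::group_by(.data$age_group) |>
    dplyr::summarise(frozen_rate = mean(.data$yearly_rate), .groups = "drop")
  if (nrow(frozen) == 0L) {
    frozen <- tibble::tibble(age_group = spec$age_groups,
                             frozen_rate = unname(spec$base_rates))
  }
  mort <- mort |>
    dplyr::left_join(frozen, by = "age_group") |>
    dplyr::mutate(yearly_rate = ifelse(.data$year >= freeze_year,
                                       .data$frozen_rate, .data$yearly_rate)) |>
    dplyr::select("year", "age_group", "yearly_rate")
  if (any(mort$yearly_rate < 0)) stop("negative mortality rate generated", call. = FALSE)

  demography(pop, mort, monthly_proportions(), scenario = spec$name)
}

#' Known ground-truth heatwave effects for parameter-recovery tests
#'
#' @param zone_logrr Named numeric: true log relative risk of death on
#'   heatwave days per climate zone.
#' @param confounder_coefs Named numeric coefficients for generic covariates.
#' @return A `true_effects` list.
#' @export
true_effects <- function(zone_logrr, confounder_coefs = numeric(0)) {
  if (any(!is.finite(zone_logrr)) || any(!is.finite(confounder_coefs))) {
    stop("effects must be finite", call. = FALSE)
  }
  structure(list(zone_logrr = zone_logrr, confounder_coefs = confounder_coefs),
            class = "true_effects")
}

#' Simulate daily death counts under a log-linear Poisson model
#'
#' Counts are drawn Poisson with
#' `log(mu) = log(baseline) + logRR * HW + sum(coef * covariate)`; used to
#' exercise the exposure-response fitter.
#'
#' @param logrr True log relative risk on heatwave days.
#' @param hw Daily 0/1 heatwave indicator.
#' @param covariates Optional data frame of numeric covariate columns, same
#'   length as `hw`.
#' @param baseline_rate Expected daily deaths on non-heatwave days at
#'   covariates = 0.
#' @param seed Integer seed.
#' @param confounder_coefs Named coefficients, one per covariate column.
#' @return Tibble with `deaths`, `hw`, and the covariate columns.
#' @export
generate_daily_mortality <- function(logrr, hw, covariates = NULL,
                                     baseline_rate = 30, seed = 1,
                                     confounder_coefs = numeric(0)) {
  hw <- as.numeric(hw)
  n <- length(hw)
  eta <- log(baseline_rate) + logrr * hw
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (nrow(covariates) != n) stop("covariates and hw lengths differ", call. = FALSE)
    if (length(confounder_coefs) != ncol(covariates) ||
        !setequal(names(confounder_coefs), names(covariates))) {
      stop("confounder_coefs must name every covariate column", call. = FALSE)
    }
    eta <- eta + as.matrix(covariates) %*% confounder_coefs[names(covariates)]
  }
  set.seed(as.integer(seed))
  out <- tibble::tibble(deaths = stats::rpois(n, exp(as.vector(eta))), hw = hw)
  if (!is.null(covariates)) out <- dplyr::bind_cols(out, covariates)
  out
}
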