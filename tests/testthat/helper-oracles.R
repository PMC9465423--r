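# Independent brute-force oracles and tiny fixture builders shared across
# the suite. The oracles deliberately avoid the package's own code paths.

# sort-and-interpolate percentile (linear interpolation between order
# statistics; same convention the threshold stage documents)
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100
  lo <- floor(h)
  if (lo + 1 >= n) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# O(n^2)-style heatwave-day scan: a day is a heatwave day iff some window
# of >= min_run consecutive exceedance days contains it
oracle_hw_indicator <- function(exceed, min_run) {
  n <- length(exceed)
  out <- logical(n)
  for (i in seq_len(n)) {
    for (start in max(1, i - min_run + 1):i) {
      end <- start + min_run - 1
      if (end > n) next
      if (all(exceed[start:end])) { out[i] <- TRUE; break }
    }
  }
  out
}

# single-cell temperature cube from an explicit daily series
cube_1cell <- function(values, years) {
  dates <- noleap_dates(years)
  stopifnot(length(values) == nrow(dates))
  temperature_cube(matrix(values, ncol = 1),
                   dates,
                   tibble::tibble(cell_id = "c001", lat = 30, lon = 110))
}

# single-cell cube with given values on specific in-season days (others cold)
cube_1cell_days <- function(year, month, day, hot, cold = 20) {
  dates <- noleap_dates(year)
  v <- rep(cold, nrow(dates))
  idx <- match(paste(month, day), paste(dates$month, dates$day))
  v[idx] <- hot
  cube_1cell(v, year)
}

# uniform one-cell demography: constant population and yearly rate
dem_1cell <- function(cell_id = "c001", years = 2000, population = 1e6,
                      yearly_rate = 0.007, monthly_prop = monthly_proportions()) {
  demography(
    tidyr::expand_grid(cell_id = cell_id, year = years) |>
      dplyr::mutate(age_group = "all", population = population),
    tidyr::expand_grid(year = years, age_group = "all") |>
      dplyr::mutate(yearly_rate = yearly_rate),
    monthly_prop
  )
}

# calendar row builder
cal_rows <- function(cell_id, year, month, hw_days) {
  tibble::tibble(cell_id = cell_id, year = year, month = month,
                 hw_days = hw_days)
}
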