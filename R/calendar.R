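# 365-day ("noleap") calendar helpers. All gridded climate handling in this
# package uses the no-leap calendar common to climate-model output; February
# always has 28 days.

.noleap_month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Days in each month of the 365-day (no-leap) calendar
#'
#' @param month Integer vector of months (1-12).
#' @return Integer vector of month lengths.
#' @export
days_in_month <- function(month = 1:12) {
  month <- as.integer(month)
  if (any(is.na(month)) || any(month < 1L | month > 12L)) {
    stop("`month` must be in 1..12", call. = FALSE)
  }
  .noleap_month_days[month]
}

#' Build a no-leap daily date table for a span of years
#'
#' @param years Integer vector of calendar years (need not be contiguous,
#'   but must be strictly increasing).
#' @return A tibble with columns `year`, `month`, `day`, `doy` (day of year,
#'   1-365), one row per day.
#' @export
noleap_dates <- function(years) {
  years <- as.integer(years)
  if (length(years) == 0L) stop("`years` must be non-empty", call. = FALSE)
  if (is.unsorted(years, strictly = TRUE)) {
    stop("`years` must be strictly increasing", call. = FALSE)
  }
  month <- rep.int(1:12, .noleap_month_days)
  day <- sequence(.noleap_month_days)
  tibble::tibble(
    year = rep(years, each = 365L),
    month = rep.int(month, length(years)),
    day = rep.int(day, length(years)),
    doy = rep.int(1:365, length(years))
  )
}

# day-of-year bounds of a month window (inclusive), no-leap calendar
season_doy_bounds <- function(season) {
  stopifnot(length(season) == 2L)
  m1 <- as.integer(season[[1]]); m2 <- as.integer(season[[2]])
  if (m1 < 1L || m2 > 12L || m1 > m2) {
    stop("season must be an increasing pair of months within 1..12", call. = FALSE)
  }
  cum <- cumsum(c(0L, .noleap_month_days))
  c(start = cum[m1] + 1L, end = cum[m2 + 1L])
}
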