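# Heatwave detection: reference-period percentile thresholds and run-length
# counting of heatwave days per grid cell, month, and year.

#' Compute per-cell reference-period percentile thresholds
#'
#' For each grid cell, pools the daily Tmax values of the reference cube
#' (by default only days inside the warm-season window, so that roughly
#' `100 - percentile` percent of in-season reference days exceed the
#' threshold) and takes the requested percentile with linear interpolation
#' between order statistics (R quantile type 7).
#'
#' @param ref A [temperature_cube()] covering the reference period.
#' @param percentile Percentile in (0, 100); default 92.5.
#' @param season Month window `c(first, last)` used both for pooling (when
#'   `season_only`) and downstream detection.
#' @param season_only If `TRUE` (default), pool only in-season days;
#'   otherwise pool the whole year.
#' @return A tibble (cell_id, threshold) with attributes `percentile`,
#'   `ref_years`, `season`, `season_only`.
#' @export
compute_threshold <- function(ref, percentile = 92.5, season = c(5, 9),
                              season_only = TRUE) {
  stopifnot(inherits(ref, "temperature_cube"))
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must be in (0, 100)", call. = FALSE)
  }
  keep <- if (season_only) {
    ref$dates$month >= season[1] & ref$dates$month <= season[2]
  } else rep(TRUE, nrow(ref$dates))
  if (!any(keep)) stop("reference cube has no days in the pooling window", call. = FALSE)
  v <- ref$values[keep, , drop = FALSE]
  thr <- apply(v, 2, stats::quantile, probs = percentile / 100,
               type = 7, names = FALSE)
  out <- tibble::tibble(cell_id = ref$cells$cell_id, threshold = unname(thr))
  attr(out, "percentile") <- percentile
  attr(out, "ref_years") <- range(ref$dates$year)
  attr(out, "season") <- season
  attr(out, "season_only") <- season_only
  out
}

# heatwave-day indicator for one cell-year's in-season exceedance vector:
# a day counts iff it sits in a maximal run of >= min_run consecutive
# exceedance days, runs evaluated inside the season window only
mark_runs <- function(exceed, min_run) {
  r <- rle(exceed)
  rep(r$values & r$lengths >= min_run, r$lengths)
}

#' Count heatwave days per grid cell, year, and month
#'
#' A heatwave is a run of at least `min_run` consecutive in-season days with
#' Tmax strictly above the cell's threshold; every day of a qualifying run
#' is a heatwave day and is allocated to the calendar month it falls in.
#' Runs are confined to the season window: the in-season portion of a spell
#' that straddles the window edge must itself reach `min_run`.
#'
#' @param cube A [temperature_cube()].
#' @param thr Threshold tibble from [compute_threshold()] (or any tibble
#'   with `cell_id`, `threshold` covering the cube's cells).
#' @param min_run Minimum run length in days (default 3).
#' @param season Month window `c(first, last)`, default May-September.
#' @return A heatwave calendar: tibble (cell_id, year, month, hw_days)
#'   complete over all cube cells, years, and in-season months, with
#'   attributes `min_run`, `season`, `scenario`, `model`.
#' @export
detect_heatwave_days <- function(cube, thr, min_run = 3, season = c(5, 9)) {
  stopifnot(inherits(cube, "temperature_cube"))
  if (min_run < 1) stop("min_run must be >= 1", call. = FALSE)
  if (!all(cube$cells$cell_id %in% thr$cell_id)) {
    stop("threshold field does not cover every cube cell", call. = FALSE)
  }
  in_season <- cube$dates$month >= season[1] & cube$dates$month <= season[2]
  if (!any(in_season)) stop("cube has no in-season days", call. = FALSE)
  thr_vec <- thr$threshold[match(cube$cells$cell_id, thr$cell_id)]

  d <- cube$dates[in_season, ]
  v <- cube$values[in_season, , drop = FALSE]
  years <- unique(d$year)
  yr_idx <- split(seq_len(nrow(d)), d$year)

  res <- vector("list", length(years) * ncol(v))
  k <- 0L
  for (yi in seq_along(years)) {
    idx <- yr_idx[[as.character(years[yi])]]
    mon <- d$month[idx]
    for (j in seq_len(ncol(v))) {
      exceed <- v[idx, j] > thr_vec[j]
      hw <- mark_runs(exceed, min_run)
      k <- k + 1L
      res[[k]] <- tibble::tibble(
        cell_id = cube$cells$cell_id[j], year = years[yi],
        month = mon[hw]
      )
    }
  }
  counts <- dplyr::bind_rows(res) |>
    dplyr::count(.data$cell_id, .data$year, .data$month, name = "hw_days")
  full <- tidyr::expand_grid(
    cell_id = cube$cells$cell_id, year = years,
    month = seq(season[1], season[2])
  )
  cal <- full |>
    dplyr::left_join(counts, by = c("cell_id", "year", "month")) |>
    dplyr::mutate(hw_days = dplyr::coalesce(.data$hw_days, 0L))
  attr(cal, "min_run") <- min_run
  attr(cal, "season") <- season
  attr(cal, "scenario") <- cube$scenario
  attr(cal, "model") <- cube$model
  cal
}

#' Summarize a heatwave calendar
#'
#' Annual totals per cell, the national mean annual heatwave days (mean over
#' cells), multi-year window means, and the fraction of cells whose
#' window-mean annual heatwave days exceed a cutoff.
#'
#' @param cal Heatwave calendar from [detect_heatwave_days()].
#' @param windows Optional named list of year ranges, e.g.
#'   `list(baseline = 1986:2005)`.
#' @param k_days Cutoff for the area-fraction statistic (default 10 days).
#' @return List with `annual_cell` (cell_id, year, hw_days), `annual_national`
#'   (year, hw_days = mean over cells), `window_cell`, `window_national`, and
#'   `area_fraction` (window, fraction of cells with mean > `k_days`).
#' @export
summarize_heatwaves <- function(cal, windows = NULL, k_days = 10) {
  annual_cell <- cal |>
    dplyr::group_by(.data$cell_id, .data$year) |>
    dplyr::summarise(hw_days = sum(.data$hw_days), .groups = "drop")
  annual_national <- annual_cell |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(hw_days = mean(.data$hw_days), .groups = "drop")
  out <- list(annual_cell = annual_cell, annual_national = annual_national)
  if (!is.null(windows)) {
    wc <- purrr::imap(windows, function(yrs, nm) {
      annual_cell |>
        dplyr::filter(.data$year %in% yrs) |>
        dplyr::group_by(.data$cell_id) |>
        dplyr::summarise(mean_hw_days = mean(.data$hw_days), .groups = "drop") |>
        dplyr::mutate(window = nm, .before = 1)
    }) |> dplyr::bind_rows()
    out$window_cell <- wc
    out$window_national <- wc |>
      dplyr::group_by(.data$window) |>
      dplyr::summarise(mean_hw_days = mean(.data$mean_hw_days), .groups = "drop")
    out$area_fraction <- wc |>
      dplyr::group_by(.data$window) |>
      dplyr::summarise(fraction = mean(.data$mean_hw_days > k_days),
                       .groups = "drop")
  }
  out
}
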