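test_that("constant reference series gives the constant as threshold", {
  cube <- cube_1cell(rep(30, 365), 2000)
  for (p in c(10, 50, 92.5, 99)) {
    expect_equal(compute_threshold(cube, p)$threshold, 30)
  }
})

test_that("threshold matches the sort-and-interpolate oracle exactly", {
  # values 1..1000 pooled over the reference days: linear interpolation
  # between the 925th and 926th order statistics gives 925.075
  vals <- rep(20, 365 * 7)
  dates <- noleap_dates(2000:2006)
  in_season <- which(dates$month >= 5 & dates$month <= 9)
  vals[in_season[1:1000]] <- 1000:1
  cube <- cube_1cell(vals, 2000:2006)
  dummy <- vals[in_season]
  expect_equal(oracle_percentile(dummy, 92.5),
               compute_threshold(cube, 92.5)$threshold, tolerance = 1e-12)
  expect_equal(oracle_percentile(1:1000, 92.5), 925.075)
  # random series, random percentiles, multiple cells
  set.seed(7)
  for (rep_i in 1:20) {
    x <- stats::rnorm(365, 25, 6)
    p <- stats::runif(1, 1, 99)
    cube <- cube_1cell(x, 2001)
    keep <- noleap_dates(2001)$month >= 5 & noleap_dates(2001)$month <= 9
    expect_equal(compute_threshold(cube, p)$threshold,
                 oracle_percentile(x[keep], p), tolerance = 1e-12)
    expect_equal(compute_threshold(cube, p, season_only = FALSE)$threshold,
                 oracle_percentile(x, p), tolerance = 1e-12)
  }
})

test_that("thresholds are per cell with no cross-cell pooling", {
  g <- tibble::tibble(cell_id = c("a", "b"), lat = c(30, 31), lon = c(110, 110))
  set.seed(3)
  v <- cbind(stats::rnorm(365, 20, 2), stats::rnorm(365, 35, 2))
  cube <- temperature_cube(v, noleap_dates(2000), g)
  thr <- compute_threshold(cube, 92.5)
  expect_equal(nrow(thr), 2)
  expect_gt(abs(diff(thr$threshold)), 5)
  expect_error(compute_threshold(cube, 0), "percentile")
  expect_error(compute_threshold(cube, 100), "percentile")
})

test_that("run-length rule counts full qualifying runs only", {
  # [31,32,33,29,31,32] vs thr 30: first 3-day run qualifies, trailing 2-day
  # run does not
  cube <- cube_1cell_days(2000, rep(6, 6), 10:15, c(31, 32, 33, 29, 31, 32))
  thr <- tibble::tibble(cell_id = "c001", threshold = 30)
  cal <- detect_heatwave_days(cube, thr, min_run = 3)
  expect_equal(sum(cal$hw_days), 3)
  expect_equal(cal$hw_days[cal$month == 6], 3)
})

test_that("no exceedance means an all-zero calendar", {
  cube <- cube_1cell(rep(20, 365), 2000)
  thr <- tibble::tibble(cell_id = "c001", threshold = 30)
  cal <- detect_heatwave_days(cube, thr)
  expect_true(all(cal$hw_days == 0))
  expect_equal(nrow(cal), 5)  # complete over in-season months
})

test_that("a run spanning a month boundary is split by calendar month", {
  # July 30 - August 3 hot: 2 days to July, 3 to August
  cube <- cube_1cell_days(2000, c(7, 7, 8, 8, 8), c(30, 31, 1, 2, 3), 35)
  thr <- tibble::tibble(cell_id = "c001", threshold = 30)
  cal <- detect_heatwave_days(cube, thr, min_run = 3)
  expect_equal(cal$hw_days[cal$month == 7], 2)
  expect_equal(cal$hw_days[cal$month == 8], 3)
  expect_equal(sum(cal$hw_days), 5)
})

test_that("spells straddling the season edge count only their in-season part", {
  # April 28 - May 2 hot: in-season part (May 1-2) is shorter than min_run
  cube <- cube_1cell_days(2000, c(4, 4, 4, 5, 5), c(28, 29, 30, 1, 2), 35)
  thr <- tibble::tibble(cell_id = "c001", threshold = 30)
  expect_equal(sum(detect_heatwave_days(cube, thr, min_run = 3)$hw_days), 0)
  # but a 3-day in-season tail does qualify
  cube2 <- cube_1cell_days(2000, c(4, 4, 5, 5, 5), c(29, 30, 1, 2, 3), 35)
  expect_equal(sum(detect_heatwave_days(cube2, thr, min_run = 3)$hw_days), 3)
  # and the same at the September/October edge
  cube3 <- cube_1cell_days(2000, c(9, 9, 10, 10), c(29, 30, 1, 2), 35)
  expect_equal(sum(detect_heatwave_days(cube3, thr, min_run = 3)$hw_days), 0)
})

test_that("detector agrees exactly with the brute-force oracle on random series", {
  set.seed(11)
  dates <- noleap_dates(2000)
  in_season <- dates$month >= 5 & dates$month <= 9
  for (i in 1:200) {
    x <- stats::rnorm(365, 28, 4)
    thr_val <- stats::runif(1, 26, 34)
    min_run <- sample(2:4, 1)
    cube <- cube_1cell(x, 2000)
    cal <- detect_heatwave_days(cube, tibble::tibble(cell_id = "c001",
                                                     threshold = thr_val),
                                min_run = min_run)
    oracle <- sum(oracle_hw_indicator(x[in_season] > thr_val, min_run))
    expect_identical(sum(cal$hw_days), oracle)
  }
})

test_that("HW counts are monotone in threshold and min_run, and in-season only", {
  set.seed(13)
  g <- make_grid(2, 2, n_zones = 2)
  cube <- generate_temperature(climate_scenario("ref", 2000:2002), g, seed = 17)
  thr <- compute_threshold(cube, 92.5)
  cal <- detect_heatwave_days(cube, thr, min_run = 3)
  expect_true(all(cal$month %in% 5:9))
  expect_true(all(cal$hw_days >= 0 & cal$hw_days <= days_in_month(cal$month)))
  # lowering the threshold never decreases any count
  thr_low <- dplyr::mutate(thr, threshold = threshold - 1.5)
  cal_low <- detect_heatwave_days(cube, thr_low, min_run = 3)
  expect_true(all(cal_low$hw_days >= cal$hw_days))
  # raising min_run never increases any count
  cal_strict <- detect_heatwave_days(cube, thr, min_run = 5)
  expect_true(all(cal_strict$hw_days <= cal$hw_days))
})

test_that("summaries conserve totals and recount the area fraction", {
  set.seed(19)
  g <- make_grid(3, 3, n_zones = 2)
  cube <- generate_temperature(climate_scenario("hot", 2000:2004, trend = 2),
                               g, seed = 23)
  thr <- compute_threshold(cube_subset_years(cube, 2000:2001))
  cal <- detect_heatwave_days(cube, thr)
  s <- summarize_heatwaves(cal, windows = list(w = 2000:2004), k_days = 10)
  # annual totals equal the sum of monthly entries
  monthly_sum <- cal |>
    dplyr::group_by(cell_id, year) |>
    dplyr::summarise(tot = sum(hw_days), .groups = "drop")
  expect_equal(dplyr::arrange(s$annual_cell, cell_id, year)$hw_days,
               dplyr::arrange(monthly_sum, cell_id, year)$tot)
  # area fraction matches a direct recount
  direct <- s$window_cell |> dplyr::summarise(f = mean(mean_hw_days > 10))
  expect_equal(s$area_fraction$fraction, direct$f)
  # single qualifying 3-day run => annual total 3
  cube1 <- cube_1cell_days(2001, c(7, 7, 7), 10:12, 35)
  cal1 <- detect_heatwave_days(cube1, tibble::tibble(cell_id = "c001",
                                                     threshold = 30))
  s1 <- summarize_heatwaves(cal1)
  expect_equal(s1$annual_cell$hw_days, 3)
})
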