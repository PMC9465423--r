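test_that("noise-free, trend-free, seasonless cube is flat at base_mean", {
  g <- make_grid(2, 2, n_zones = 2, base_mean_south = 25, lapse = 0.5)
  spec <- climate_scenario("ref", 1990:1991, trend = 0, sigma = 0,
                           seasonal_amp = 0)
  cube <- generate_temperature(spec, g, seed = 1)
  for (j in seq_len(4)) {
    expect_equal(unname(cube$values[, j]), rep(g$base_mean[j], 730))
  }
})

test_that("temperature generation is bit-identical under the same seed", {
  g <- make_grid(3, 3, n_zones = 2)
  spec <- climate_scenario("low", 2000:2004, trend = 0.2)
  c1 <- generate_temperature(spec, g, seed = 99)
  c2 <- generate_temperature(spec, g, seed = 99)
  expect_identical(c1$values, c2$values)
  c3 <- generate_temperature(spec, g, seed = 100)
  expect_false(identical(c1$values, c3$values))
})

test_that("OLS on annual means recovers the imposed warming trend", {
  # slope of annual means per replicate run; the spread across independent
  # replicates gives an honest standard error for the mean slope (the AR(1)
  # noise leaves mild dependence between annual means within one run)
  g <- make_grid(1, 2, n_zones = 2)
  spec <- climate_scenario("high", 2001:2100, trend = 0.5, sigma = 2, rho = 0.7)
  slopes <- vapply(1:5, function(s) {
    cube <- generate_temperature(spec, g, seed = s)
    annual <- tapply(cube$values[, 1], cube$dates$year, mean)
    yrs <- as.numeric(names(annual))
    unname(stats::coef(stats::lm(annual ~ yrs))["yrs"])
  }, numeric(1))
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.05), 3 * se)
})

test_that("scenario validation rejects bad parameters", {
  expect_error(climate_scenario("x", 2000, rho = 1), "rho")
  expect_error(climate_scenario("x", 2000, sigma = -1), "sigma")
  expect_error(climate_scenario("x", 2000, trend = NaN), "finite")
  expect_error(climate_scenario("x", integer(0)), "non-empty")
})

test_that("population trajectory peaks at peak_year and aging is linear", {
  g <- make_grid(2, 2, n_zones = 2)
  spec <- population_scenario("medium", peak_year = 2032, aging_rate = 0.002)
  dem <- generate_population(spec, g, 1986:2100, seed = 3)
  tot <- dem$population |>
    dplyr::group_by(year) |>
    dplyr::summarise(p = sum(population))
  expect_equal(tot$year[which.max(tot$p)], 2032)
  # monotone rise to the peak, monotone decline after
  expect_true(all(diff(tot$p[tot$year <= 2032]) > 0))
  expect_true(all(diff(tot$p[tot$year >= 2032]) < 0))
  share_old <- dem$population |>
    dplyr::group_by(year) |>
    dplyr::summarise(s = sum(population[age_group == "75+"]) / sum(population))
  expect_equal(diff(share_old$s), rep(0.002, 114), tolerance = 1e-9)
})

test_that("aging_rate = 0 keeps shares constant; late peak gives monotone totals", {
  g <- make_grid(1, 2, n_zones = 2)
  dem0 <- generate_population(population_scenario(aging_rate = 0), g,
                              2000:2020, seed = 4)
  sh <- dem0$population |>
    dplyr::group_by(year, age_group) |>
    dplyr::summarise(p = sum(population), .groups = "drop_last") |>
    dplyr::mutate(share = p / sum(p)) |>
    dplyr::ungroup()
  expect_equal(dplyr::n_distinct(round(sh$share, 12)), 3)
  dem_late <- generate_population(population_scenario(peak_year = 2020), g,
                                  2000:2020, seed = 4)
  tot <- dem_late$population |>
    dplyr::group_by(year) |>
    dplyr::summarise(p = sum(population))
  expect_true(all(diff(tot$p) >= 0))
})

test_that("mortality rates are frozen at the 2010s mean from the freeze year", {
  g <- make_grid(1, 2, n_zones = 2)
  dem <- generate_population(population_scenario(), g, 1986:2100, seed = 8)
  future <- dem$mortality |> dplyr::filter(year >= 2020)
  per_group <- future |>
    dplyr::group_by(age_group) |>
    dplyr::summarise(n = dplyr::n_distinct(yearly_rate))
  expect_true(all(per_group$n == 1))
  mean_2010s <- dem$mortality |>
    dplyr::filter(year %in% 2010:2019, age_group == "75+") |>
    dplyr::pull(yearly_rate) |> mean()
  frozen <- unique(future$yearly_rate[future$age_group == "75+"])
  expect_equal(frozen, mean_2010s)
})

test_that("demographic closure: age groups sum to the cell-year total", {
  g <- make_grid(2, 2, n_zones = 2)
  spec <- population_scenario()
  dem <- generate_population(spec, g, 2000:2010, seed = 6)
  by_cell <- dem$population |>
    dplyr::group_by(cell_id, year) |>
    dplyr::summarise(p = sum(population), .groups = "drop")
  national <- by_cell |> dplyr::group_by(year) |> dplyr::summarise(p = sum(p))
  # shares sum to 1 per cell-year => cell totals are share-free
  shares <- dem$population |>
    dplyr::inner_join(by_cell, by = c("cell_id", "year")) |>
    dplyr::group_by(cell_id, year) |>
    dplyr::summarise(s = sum(population / p), .groups = "drop")
  expect_true(all(abs(shares$s - 1) < 1e-9))
  expect_true(all(national$p > 0))
})

test_that("null daily mortality has the right mean and rejects bad input", {
  n <- 5000
  hw <- rep(c(0, 1), length.out = n)
  dd <- generate_daily_mortality(logrr = 0, hw = hw, baseline_rate = 30,
                                 seed = 2)
  expect_lt(abs(mean(dd$deaths) - 30), 3 * sqrt(30 / n))
  expect_error(
    generate_daily_mortality(0.1, hw, covariates = data.frame(x = 1:10),
                             confounder_coefs = c(x = 0.1)),
    "length"
  )
})

test_that("reference-run threshold is exceeded on about 7.5% of in-season days", {
  g <- make_grid(3, 3, n_zones = 2)
  spec <- climate_scenario("ref", 1986:2005, trend = 0, sigma = 2, rho = 0.7)
  cube <- generate_temperature(spec, g, seed = 21)
  thr <- compute_threshold(cube, 92.5)
  in_season <- cube$dates$month >= 5 & cube$dates$month <= 9
  exc <- vapply(seq_len(ncol(cube$values)), function(j) {
    mean(cube$values[in_season, j] > thr$threshold[j])
  }, numeric(1))
  n <- sum(in_season)
  expect_true(all(abs(exc - 0.075) < 4 * sqrt(0.075 * 0.925 / n) + 1 / n))
})
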