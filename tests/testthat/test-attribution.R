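test_that("attributable fraction follows (RR-1)/RR", {
  expect_equal(attributable_fraction(1), 0, ignore_attr = TRUE)
  expect_equal(attributable_fraction(2), 0.5, ignore_attr = TRUE)
  expect_equal(attributable_fraction(1.08), (1.08 - 1) / 1.08,
               ignore_attr = TRUE)
  expect_equal(attributable_fraction(1.08), 0.0740740740740741,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(attributable_fraction(0), "> 0")
  expect_error(attributable_fraction(-1), "> 0")
  # protective RRs floored at 0 with a warning, unless allowed
  expect_warning(af <- attributable_fraction(c(0.9, 1.2)), "floored")
  expect_equal(as.numeric(af), c(0, 1 - 1 / 1.2))
  expect_equal(attr(af, "n_floored"), 1L)
  af2 <- attributable_fraction(0.9, allow_protective = TRUE)
  expect_lt(af2, 0)
  # monotone increasing in RR
  rr <- seq(1, 3, by = 0.1)
  expect_true(all(diff(attributable_fraction(rr)) > 0))
})

test_that("the attributable-number formula matches the hand-evaluated toy", {
  # Pop 1e6, yearly rate 0.007, July proportion 1/12 over 31 days,
  # 10 heatwave days in July, AF 0.05 -> 1e6*(0.007/12/31)*10*0.05
  mp <- tibble::tibble(month = 1:12, proportion = rep(1 / 12, 12))
  dem <- dem_1cell(years = 2000, population = 1e6, yearly_rate = 0.007,
                   monthly_prop = mp)
  cal <- cal_rows("c001", 2000, 5:9, c(0, 0, 10, 0, 0))
  af <- tibble::tibble(cell_id = "c001", af = 0.05)
  res <- attributable_deaths(dem, cal, af)
  expect_equal(res$an, 1e6 * 0.007 / 12 / 31 * 10 * 0.05, tolerance = 1e-12)
  expect_equal(res$an, 9.4086, tolerance = 1e-4)
})

test_that("AN is zero when AF is zero and linear in each ingredient", {
  mp <- monthly_proportions()
  dem <- dem_1cell(years = 2000:2001, monthly_prop = mp)
  cal <- tidyr::expand_grid(cell_id = "c001", year = 2000:2001, month = 5:9) |>
    dplyr::mutate(hw_days = c(3, 0, 5, 2, 0, 0, 4, 0, 0, 1))
  af0 <- tibble::tibble(cell_id = "c001", af = 0)
  expect_true(all(attributable_deaths(dem, cal, af0)$an == 0))
  af <- tibble::tibble(cell_id = "c001", af = 0.06)
  base <- attributable_deaths(dem, cal, af)
  # doubling population doubles AN exactly
  dem2 <- dem_1cell(years = 2000:2001, population = 2e6, monthly_prop = mp)
  expect_equal(attributable_deaths(dem2, cal, af)$an, 2 * base$an)
  # scaling the mortality rate scales AN
  dem3 <- dem_1cell(years = 2000:2001, yearly_rate = 3 * 0.007,
                    monthly_prop = mp)
  expect_equal(attributable_deaths(dem3, cal, af)$an, 3 * base$an)
  # scaling HW days scales AN
  cal4 <- dplyr::mutate(cal, hw_days = 4 * hw_days)
  expect_equal(attributable_deaths(dem, cal4, af)$an, 4 * base$an)
  # scaling AF scales AN
  af5 <- dplyr::mutate(af, af = 5 * af)
  expect_equal(attributable_deaths(dem, cal, af5)$an, 5 * base$an)
  # a zero-heatwave year gives zero AN
  expect_equal(base$an[base$year == 2001],
               attributable_deaths(dem, cal, af)$an[2])
  cal_zero <- dplyr::mutate(cal, hw_days = ifelse(year == 2001, 0, hw_days))
  expect_equal(attributable_deaths(dem, cal_zero, af)$an[2], 0)
})

test_that("AN is additive over cells and age stratification sums groups", {
  mp <- monthly_proportions()
  pop <- tidyr::expand_grid(cell_id = c("a", "b"), year = 2000,
                            age_group = c("young", "old")) |>
    dplyr::mutate(population = c(8e5, 2e5, 6e5, 4e5))
  mort <- tidyr::expand_grid(year = 2000, age_group = c("young", "old")) |>
    dplyr::mutate(yearly_rate = c(0.003, 0.05))
  dem <- demography(pop, mort, mp)
  cal <- cal_rows(rep(c("a", "b"), each = 5), 2000, rep(5:9, 2),
                  c(2, 0, 6, 1, 0, 0, 3, 3, 0, 0))
  af <- tibble::tibble(cell_id = c("a", "b"), af = c(0.05, 0.08))
  res <- attributable_deaths(dem, cal, af)
  # additivity: national = sum over cells; recompute cell "a" by hand over
  # age groups and months
  daily <- mp$proportion / days_in_month(1:12)
  base_a <- 8e5 * 0.003 + 2e5 * 0.05
  an_a <- base_a * 0.05 * sum(daily[5:9] * c(2, 0, 6, 1, 0))
  expect_equal(res$an[res$cell_id == "a"], an_a, tolerance = 1e-12)
  expect_equal(sum(res$an),
               decade_average(res, 2000, by = "nation")$an)
})

test_that("decade averages recount and reject partial windows", {
  res <- tidyr::expand_grid(cell_id = c("a", "b"), year = 1986:2005) |>
    dplyr::mutate(an = ifelse(cell_id == "a", 7, year - 1985))
  d <- decade_average(res, 1986:2005, by = "cell")
  expect_equal(d$an[d$cell_id == "a"], 7)
  expect_equal(d$an[d$cell_id == "b"], mean(1:20))
  expect_equal(decade_average(res, 1986:2005, by = "nation")$an,
               7 + mean(1:20))
  # recount oracle: window mean equals sum/20
  expect_equal(d$an[d$cell_id == "b"], sum(1:20) / 20)
  expect_error(decade_average(res, 1986:2010), "not covered")
  # values outside the window cannot influence the window mean
  res2 <- dplyr::mutate(res, an = ifelse(year < 1990, an + 100, an))
  expect_equal(decade_average(res, 1990:2005, by = "nation"),
               decade_average(res2, 1990:2005, by = "nation"))
  # regional aggregation
  regions <- tibble::tibble(cell_id = c("a", "b"), region = c("N", "S"))
  dr <- decade_average(res, 1986:2005, by = "region", regions = regions)
  expect_equal(sort(dr$an), sort(c(7, mean(1:20))))
})

test_that("growth rate follows (future - baseline)/baseline * 100", {
  expect_equal(growth_rate(10, 10), 0)
  expect_equal(growth_rate(30, 10), 200)
  expect_error(growth_rate(5, 0), "baseline")
  expect_error(growth_rate(5, -2), "baseline")
})

test_that("scenario differences subtract elementwise and add up", {
  a <- tibble::tibble(cell_id = c("a", "b"), an = c(10, 20))
  b <- tibble::tibble(cell_id = c("a", "b"), an = c(4, 5))
  d <- scenario_difference(a, b)
  expect_equal(d$an_diff, c(6, 15))
  expect_equal(sum(d$an_diff),
               scenario_difference(
                 tibble::tibble(unit = "nation", an = sum(a$an)),
                 tibble::tibble(unit = "nation", an = sum(b$an)))$an_diff)
  expect_equal(scenario_difference(a, a)$an_diff, c(0, 0))
  expect_error(scenario_difference(a, b[1, ]), "units")
})
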