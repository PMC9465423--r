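# End-to-end driver: synthetic climate + demography generation, heatwave
# detection, exposure-response fitting and pooling, attribution, Monte-Carlo
# uncertainty, driver decomposition, and the summary report. A single root
# seed fans out to per-stage substreams; all stage outputs are written as
# CSV alongside a metadata table carrying the config hash and seeds.

#' Default pipeline configuration
#'
#' The shipped demo configuration: a 6x6 half-degree grid in 4 climate
#' zones; three emission scenarios (low/mid/high warming trend) times two
#' synthetic climate-model members over 1986-2100; three fertility
#' scenarios for population; per-zone true log relative risks recovered by
#' the Poisson stage; the four 20-year analysis windows; 1,000 Monte-Carlo
#' coefficient samples.
#'
#' @param seed Root seed.
#' @return Nested config list (YAML-serializable).
#' @export
default_config <- function(seed = 42) {
  list(
    seed = as.integer(seed),
    grid = list(nx = 6, ny = 6, lat0 = 22, lon0 = 105, spacing = 0.5,
                n_zones = 4, base_mean_south = 24, lapse = 0.8),
    years = c(1986, 2100),
    ref_years = c(1986, 2005),
    percentile = 92.5,
    min_run = 3,
    season = c(5, 9),
    models = c("m1", "m2"),
    scenarios = list(
      low = list(trend = 0.10, sigma = 2, rho = 0.7, seasonal_amp = 10),
      mid = list(trend = 0.25, sigma = 2, rho = 0.7, seasonal_amp = 10),
      high = list(trend = 0.50, sigma = 2, rho = 0.7, seasonal_amp = 10)
    ),
    windows = list(baseline = c(1986, 2005), y2030 = c(2021, 2040),
                   y2060 = c(2051, 2070), y2090 = c(2081, 2100)),
    population = list(
      low = list(peak_year = 2028, peak_ratio = 1.08, aging_rate = 0.002),
      medium = list(peak_year = 2032, peak_ratio = 1.15, aging_rate = 0.002),
      high = list(peak_year = 2038, peak_ratio = 1.25, aging_rate = 0.002)
    ),
    rr = list(
      zone_logrr = c(Z1 = 0.05, Z2 = 0.07, Z3 = 0.09, Z4 = 0.11),
      sites_per_zone = 3, n_days = 2500, hw_prob = 0.10, baseline_rate = 30,
      alpha_q = 0.05
    ),
    mc = list(n_samples = 1000, percentiles = c(2.5, 97.5)),
    uncertainty = list(n_rr_levels = 50)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [default_config()].
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

# mean heatwave calendar across ensemble members
average_calendars <- function(cals) {
  dplyr::bind_rows(cals, .id = "member") |>
    dplyr::group_by(.data$cell_id, .data$year, .data$month) |>
    dplyr::summarise(hw_days = mean(.data$hw_days), .groups = "drop")
}

#' Run the full heatwave-attribution pipeline on synthetic inputs
#'
#' Executes every stage in order — simulate, detect, fit, attribute,
#' uncertainty, decompose, report — and writes the stage outputs as CSV to
#' `out_dir`. Deterministic given `config$seed`.
#'
#' @param config Config list from [default_config()] or [read_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return (Invisibly) a list with the grid, zone RRs, per-model/scenario
#'   calendars, national summary (point, CI, growth per scenario/window),
#'   avoided deaths vs the stabilized low-warming climate, driver
#'   decompositions, and uncertainty shares.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("heatattrib_"),
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg_hash <- rlang::hash(config)
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 2, 512)
  years <- seq(config$years[1], config$years[2])
  ref_years <- seq(config$ref_years[1], config$ref_years[2])
  windows <- purrr::map(config$windows, ~ seq(.x[1], .x[2]))
  season <- config$season

  ## -- simulate: grid, climate cubes, demography ---------------------------
  g <- config$grid
  grid <- stage("simulate", make_grid(g$nx, g$ny, g$lat0, g$lon0, g$spacing,
                                      g$n_zones, g$base_mean_south, g$lapse))
  write_zone_csv(grid, file.path(out_dir, "zones.csv"))
  zone_levels <- sort(unique(grid$zone))

  cubes <- stage("simulate", {
    si <- 0L
    purrr::map(stats::setNames(config$models, config$models), function(m) {
      purrr::imap(config$scenarios, function(sc, nm) {
        si <<- si + 1L
        spec <- climate_scenario(nm, years, trend = sc$trend, sigma = sc$sigma,
                                 rho = sc$rho, seasonal_amp = sc$seasonal_amp)
        generate_temperature(spec, grid, seed = seeds[si], model = m)
      })
    })
  })
  say("simulate: %d cells, %d model runs x %d scenarios, %d-%d",
      nrow(grid), length(config$models), length(config$scenarios),
      min(years), max(years))

  dems <- stage("simulate", {
    purrr::imap(config$population, function(ps, nm) {
      spec <- population_scenario(nm, peak_year = ps$peak_year,
                                  peak_ratio = ps$peak_ratio,
                                  aging_rate = ps$aging_rate)
      generate_population(spec, grid, years,
                          seed = seeds[31 + match(nm, names(config$population))])
    })
  })
  central_pop <- if ("medium" %in% names(dems)) "medium" else
    names(dems)[ceiling(length(dems) / 2)]
  dem_med <- dems[[central_pop]]
  write_demography_csv(dem_med, out_dir, prefix = central_pop)

  ## -- detect: thresholds + heatwave calendars -----------------------------
  calendars <- stage("detect", {
    purrr::map(cubes, function(by_scen) {
      purrr::map(by_scen, function(cube) {
        ref <- cube_subset_years(cube, ref_years)
        thr <- compute_threshold(ref, percentile = config$percentile,
                                 season = season)
        detect_heatwave_days(cube, thr, min_run = config$min_run,
                             season = season)
      })
    })
  })
  n_hw <- sum(purrr::map_dbl(calendars, ~ sum(purrr::map_dbl(.x, ~ sum(.x$hw_days)))))
  say("detect: %.0f heatwave cell-days across all runs", n_hw)

  ## -- fit: site-level Poisson RRs, zone pooling, grid mapping -------------
  rrcfg <- config$rr
  site_fits <- stage("fit", {
    si <- 100L
    purrr::map(zone_levels, function(z) {
      purrr::map(seq_len(rrcfg$sites_per_zone), function(s) {
        si <<- si + 1L
        set.seed(seeds[si])
        hw <- stats::rbinom(rrcfg$n_days, 1, rrcfg$hw_prob)
        covs <- data.frame(x1 = stats::rnorm(rrcfg$n_days),
                           x2 = stats::rnorm(rrcfg$n_days))
        dd <- generate_daily_mortality(
          logrr = rrcfg$zone_logrr[[z]], hw = hw, covariates = covs,
          baseline_rate = rrcfg$baseline_rate, seed = seeds[si],
          confounder_coefs = c(x1 = 0.02, x2 = -0.01)
        )
        fit_poisson_rr(dd$deaths, dd$hw, dd[, c("x1", "x2")],
                       unit = sprintf("%s_site%d", z, s)) |>
          dplyr::mutate(zone = z)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
  zone_rrs <- stage("fit", pool_all_zones(site_fits, alpha_q = rrcfg$alpha_q))
  rr_cells <- stage("fit", map_rr_to_grid(zone_rrs, grid))
  write_rr_csv(zone_rrs, file.path(out_dir, "rr_zone.csv"))
  say("fit: %d sites pooled to %d zones (models: %s)",
      nrow(site_fits), nrow(zone_rrs), paste(zone_rrs$model_used, collapse = "/"))

  af_field <- rr_cells |>
    dplyr::mutate(af = attributable_fraction(.data$rr)) |>
    dplyr::select("cell_id", "af")
  rates_frozen <- dem_med$mortality |>
    dplyr::filter(.data$year == max(.data$year)) |>
    dplyr::select("age_group", "yearly_rate")

  ## -- attribute + uncertainty: national AN per scenario/window with CI ----
  summary_rows <- list()
  mc_results <- list()
  for (sc in names(config$scenarios)) {
    cals_sc <- purrr::map(calendars, ~ .x[[sc]])
    for (w in names(windows)) {
      mc <- stage("uncertainty", mc_attributable(
        rr_cells, cals_sc, dem_med, windows[[w]],
        n_samples = config$mc$n_samples,
        seed = seeds[300 + match(sc, names(config$scenarios)) * 10 +
                       match(w, names(windows))],
        percentiles = config$mc$percentiles
      ))
      mc_results[[paste(sc, w, sep = ".")]] <- mc
      summary_rows[[paste(sc, w, sep = ".")]] <- tibble::tibble(
        scenario = sc, window = w, an = mc$point,
        ci_low = mc$ci_low, ci_high = mc$ci_high
      )
    }
  }
  national <- dplyr::bind_rows(summary_rows) |>
    dplyr::group_by(.data$scenario) |>
    dplyr::mutate(growth_pct = ifelse(
      .data$window == "baseline", 0,
      growth_rate(.data$an, .data$an[.data$window == "baseline"])
    )) |>
    dplyr::ungroup()
  say("attribute: national AN computed for %d scenario x window combinations",
      nrow(national))

  ## -- 1.5 degree analogue: stabilized low-warming climate (early-century
  ##    window of the lowest-trend scenario) paired with end-of-century
  ##    demography ----------------------------------------------------------
  ev <- make_an_evaluator(af_field, rates_frozen, dem_med$monthly_prop)
  stab_scen <- names(config$scenarios)[
    which.min(purrr::map_dbl(config$scenarios, "trend"))]
  stab_window <- if (length(windows) >= 2) windows[[2]] else windows[[1]]
  target_name <- names(windows)[length(windows)]
  mean_cal_stab <- average_calendars(purrr::map(calendars, ~ .x[[stab_scen]]))
  climate_15 <- build_factor_state(dem_med, mean_cal_stab, stab_window)$climate
  state_target <- build_factor_state(dem_med,
                                     average_calendars(purrr::map(calendars, ~ .x[[1]])),
                                     windows[[target_name]])
  an_15 <- stage("attribute", ev(climate_15, state_target$size, state_target$aging))
  avoided <- national |>
    dplyr::filter(.data$window == target_name) |>
    dplyr::transmute(scenario = .data$scenario, an_target = .data$an,
                     an_15 = an_15, avoided_deaths = .data$an - an_15)

  ## -- decompose: climate / size / aging driver contributions -------------
  wn <- names(windows)
  period_pairs <- purrr::map(seq_len(length(wn) - 1),
                             ~ c(wn[.x], wn[.x + 1]))
  if (length(wn) > 2) period_pairs <- c(period_pairs, list(c(wn[1], wn[length(wn)])))
  drivers <- stage("decompose", {
    purrr::map(names(config$scenarios), function(sc) {
      mean_cal <- average_calendars(purrr::map(calendars, ~ .x[[sc]]))
      purrr::map(period_pairs, function(pp) {
        s1 <- build_factor_state(dem_med, mean_cal, windows[[pp[1]]])
        s2 <- build_factor_state(dem_med, mean_cal, windows[[pp[2]]])
        res <- decompose_change(s1, s2, ev)
        sh <- contribution_shares(res)
        sh |>
          dplyr::mutate(scenario = sc, from = pp[1], to = pp[2],
                        total_change = res$total, .before = 1)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })

  ## -- uncertainty sources: RR parameters vs climate models vs population -
  shares <- stage("uncertainty", {
    zones <- rr_cells |> dplyr::distinct(.data$zone, .data$beta, .data$se)
    set.seed(seeds[200])
    n_lv <- config$uncertainty$n_rr_levels
    rr_levels <- purrr::map(seq_len(n_lv), function(i) {
      stats::setNames(stats::rnorm(nrow(zones), zones$beta, zones$se), zones$zone)
    })
    purrr::map(names(config$scenarios), function(sc) {
      model_climates <- purrr::map(calendars, function(by_scen) {
        build_factor_state(dem_med, by_scen[[sc]], windows[[target_name]])$climate
      })
      central_climate <- build_factor_state(
        dem_med, average_calendars(purrr::map(calendars, ~ .x[[sc]])),
        windows[[target_name]])$climate
      pop_states <- purrr::map(dems, function(d) {
        st <- build_factor_state(d, average_calendars(purrr::map(calendars, ~ .x[[sc]])),
                                 windows[[target_name]])
        list(size = st$size, aging = st$aging)
      })
      an_fun <- function(rr_parameters, climate_models, population_scenarios) {
        af <- grid |>
          dplyr::transmute(cell_id = .data$cell_id,
                           af = attributable_fraction(exp(rr_parameters[.data$zone])))
        ev2 <- make_an_evaluator(af, rates_frozen, dem_med$monthly_prop)
        ev2(climate_models, population_scenarios$size, population_scenarios$aging)
      }
      decompose_uncertainty(
        an_fun,
        source_levels = list(rr_parameters = rr_levels,
                             climate_models = model_climates,
                             population_scenarios = pop_states),
        central = list(rr_parameters = stats::setNames(zones$beta, zones$zone),
                       climate_models = central_climate,
                       population_scenarios = pop_states[[central_pop]])
      ) |> dplyr::mutate(scenario = sc, .before = 1)
    }) |> dplyr::bind_rows()
  })

  ## -- report --------------------------------------------------------------
  meta <- tibble::tibble(config_hash = cfg_hash, seed = config$seed,
                         n_cells = nrow(grid), n_models = length(config$models),
                         n_mc_samples = config$mc$n_samples)
  readr::write_csv(meta, file.path(out_dir, "run_metadata.csv"))
  readr::write_csv(dplyr::mutate(national, config_hash = cfg_hash),
                   file.path(out_dir, "an_national.csv"))
  readr::write_csv(dplyr::mutate(avoided, config_hash = cfg_hash),
                   file.path(out_dir, "avoided_15.csv"))
  readr::write_csv(dplyr::mutate(drivers, config_hash = cfg_hash),
                   file.path(out_dir, "drivers.csv"))
  readr::write_csv(dplyr::mutate(shares, config_hash = cfg_hash),
                   file.path(out_dir, "uncertainty_shares.csv"))
  for (m in names(calendars)) {
    for (sc in names(calendars[[m]])) {
      write_calendar_csv(calendars[[m]][[sc]],
                         file.path(out_dir, sprintf("hw_%s_%s.csv", m, sc)))
    }
  }
  say("report: outputs written to %s", out_dir)

  invisible(list(
    grid = grid, config_hash = cfg_hash, calendars = calendars,
    site_fits = site_fits, zone_rrs = zone_rrs, rr_cells = rr_cells,
    af_field = af_field, demography = dems, national = national,
    mc = mc_results, an_15 = an_15, avoided = avoided, drivers = drivers,
    uncertainty_shares = shares, out_dir = out_dir
  ))
}
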