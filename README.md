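# heatattrib

Projection of heatwave-attributable mortality under climate and population
change, for epidemiologists and climate-health modellers who need a tested,
reusable pipeline rather than one-off scripts.

Given gridded daily maximum temperature (reference period plus future
scenario runs), age-structured population, baseline mortality rates, and
daily death counts (or pre-estimated relative risks), the package:

1. **detects heatwaves** — per-cell thresholds at the 92.5th percentile of
   reference-period Tmax; a heatwave is ≥ 3 consecutive days strictly above
   threshold within May–September;
2. **estimates exposure-response** — Poisson regression
   log μ_t = α + β·HW_t + Σ γ_j x_jt per location, pooled to climate zones
   by inverse-variance meta-analysis with the Cochran-Q / I² ≥ 50% rule for
   switching to DerSimonian–Laird random effects;
3. **attributes deaths** — AF = (RR − 1)/RR and

   AN_{y,p} = Σ_m Pop_{y,p} · Mort_{d,m,y,p} · HW_{m,y,p} · AF_{y,p},

   where Mort_{d,m,y,p} is the yearly baseline rate × monthly mortality
   proportion ÷ days in month, m over May–September, with 20-year window
   averages and growth rates (future − baseline)/baseline × 100%;
4. **propagates uncertainty** — 1,000 Monte-Carlo draws of β per zone,
   pooled with climate-model ensemble members into empirical 2.5/97.5%
   intervals, plus a partition of total variance among RR parameters,
   climate models, and population scenarios;
5. **decomposes drivers** — the change in burden between two periods split
   into climate, population-size, and aging contributions by sequential
   factor substitution averaged over all 3! orderings (exactly additive).

A synthetic-data module (seasonal cycle + AR(1) noise + warming trend
temperature fields; age-structured population trajectories with a
mid-century peak and an aging trend; Poisson death counts with known true
RRs) makes every stage runnable and testable offline. See the methods
vignette (`vignettes/methods.Rmd`) for the modelling choices and their
rationale.

## Worked example

Sixteen cells, one climate zone, a 0.5 °C/decade warming run against a
1986–2005 reference, three synthetic monitoring sites with true
log RR = 0.08:

```r
library(heatattrib)

grid <- make_grid(4, 4, n_zones = 2) |> dplyr::mutate(zone = "Z1")
ref  <- generate_temperature(climate_scenario("ref", 1986:2005), grid, seed = 10)
fut  <- generate_temperature(climate_scenario("high", 1986:2100, trend = 0.5),
                             grid, seed = 11)
thr <- compute_threshold(ref, percentile = 92.5)
cal <- detect_heatwave_days(fut, thr, min_run = 3)
summarize_heatwaves(cal, windows = list(baseline = 1986:2005,
                                        late = 2081:2100))$window_national
#>   window   mean_hw_days
#> 1 baseline         9.43
#> 2 late            73.0

sites <- dplyr::bind_rows(lapply(1:3, function(i) {
  set.seed(i); hw <- rbinom(2500, 1, 0.1)
  dd <- generate_daily_mortality(0.08, hw, baseline_rate = 30, seed = i)
  fit_poisson_rr(dd$deaths, dd$hw, unit = paste0("site", i))
}))
pool_zone(sites, unit = "Z1")
#>   zone    beta      se    rr    I2 model_used
#> 1 Z1    0.0787 0.00671  1.08  37.9 fixed

rr_cells <- map_rr_to_grid(dplyr::rename(pool_zone(sites, unit = "Z1"),
                                         zone = unit), grid)
af  <- dplyr::transmute(rr_cells, cell_id, af = attributable_fraction(rr))
dem <- generate_population(population_scenario(), grid, 1986:2100, seed = 12)
an  <- attributable_deaths(dem, cal, af)
mc  <- mc_attributable(rr_cells, list(m1 = cal), dem, 2081:2100,
                       n_samples = 1000, seed = 13)
```

The baseline-window national burden is 152 attributable deaths per year;
by 2081–2100 it reaches 2227.7 (95% CI 1871.3–2560.8), a growth rate of
1365.6% — heatwave days rise ~8-fold while the population both peaks and
ages. The pooled RR of 1.08 means 8% excess mortality on heatwave days;
its attributable fraction (RR − 1)/RR ≈ 0.076 is the share of heatwave-day
deaths charged to heat. The confidence interval reflects coefficient
uncertainty only (one model run here); with an ensemble, member spread
enters the same empirical distribution.

The full pipeline — all stages, three scenarios, ensembles, decompositions —
runs from one config:

```r
res <- run_pipeline(read_config(system.file("extdata", "demo_config.yaml",
                                            package = "heatattrib")),
                    out_dir = "pipeline_out")
```

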