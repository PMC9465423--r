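---
title: "Methods: projecting heatwave-attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting heatwave-attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatattrib)
```

## The estimation problem

Heatwaves raise short-term mortality. Given (i) gridded daily maximum
temperature for a reference period and one or more future scenario runs,
(ii) gridded age-structured population and baseline mortality rates, and
(iii) an estimate of the relative risk (RR) of death on heatwave days,
`heatattrib` projects the yearly number of deaths attributable to heatwaves
per grid cell, aggregates it over 20-year windows, attaches Monte-Carlo
confidence intervals, and decomposes changes in the burden into climate,
population-size, and aging contributions.

The chain is:

1. **Heatwave definition.** A per-cell threshold is the 92.5th percentile of
   daily Tmax over the reference period; a heatwave is a run of at least 3
   consecutive days strictly above the threshold inside the May–September
   warm season. `detect_heatwave_days()` returns HW~m,y,p~, the count of
   heatwave days in month *m*, year *y*, cell *p*.
2. **Exposure-response.** Location-level Poisson regression,
   log μ~t~ = α + β·HW~t~ + Σ γ~j~ x~jt~, gives β = log RR per site;
   sites are pooled to climate zones by inverse-variance meta-analysis, and
   zone RRs are mapped back onto the grid.
3. **Attribution.** AF = (RR − 1)/RR and
   AN~y,p~ = Σ~m~ Pop~y,p~ · Mort~d,m,y,p~ · HW~m,y,p~ · AF~y,p~, where the
   daily rate Mort~d,m,y,p~ is the yearly baseline rate times the monthly
   mortality proportion divided by the days in month *m*, and *m* runs over
   May–September. With age-structured demography the Pop·Mort product is
   summed over age groups.
4. **Uncertainty.** β is resampled from Normal(β̂, SE) 1,000 times per zone;
   the AN distribution over draws × climate-model ensemble members yields
   empirical 2.5th/97.5th-percentile intervals around the ensemble-mean
   point estimate.
5. **Drivers.** The change in window-average AN between two periods is
   split into climate (the heatwave calendar), population size, and aging
   (the age-share vector) by switching one factor at a time along every
   ordering of the three factors and averaging — a Shapley decomposition,
   so the parts sum exactly to the whole.

## Design choices where the method is underdetermined

Several details are not pinned down by the one-sentence definitions common
in the applied literature; the package fixes them as follows.

* **Threshold locality.** Percentile thresholds are computed per grid cell,
  never pooled across cells; heat tolerance is a local property and the
  zone-specific framing of the RRs presumes local baselines.
* **Pooling window for the percentile.** By default the percentile is taken
  over in-season (May–September) reference days, so that about 7.5% of
  in-season days exceed it; `season_only = FALSE` switches to the all-year
  pool for sensitivity analysis. The all-year convention yields higher
  thresholds and fewer heatwave days.
* **Percentile convention.** Linear interpolation between order statistics
  (R's default quantile type 7). The test suite pins the implementation to
  an independent sort-and-interpolate oracle under the same convention.
* **Exceedance is strict** (`>` not `>=`).
* **Month allocation.** Every day of a qualifying run counts, allocated to
  the calendar month it falls in; this is what makes AN's month-indexed sum
  well defined when a run straddles a month boundary.
* **Season confinement.** Runs are evaluated inside the season window; the
  in-season portion of a spell straddling April 30 or October 1 must itself
  reach the minimum run length. A 3-day spell ending May 1 therefore counts
  zero heatwave days.
* **Model-choice rule in pooling.** Cochran's Q on k−1 df and
  I² = max(0, (Q−(k−1))/Q)·100; random effects (DerSimonian–Laird moment
  estimator) only when the Q test is significant at α = 0.05 *and*
  I² ≥ 50%, otherwise fixed effects. DL is standard and non-iterative;
  REML would be the natural alternative.
* **Protective RRs.** AF < 0 (RR < 1) is floored at zero by default with a
  warning counter, treating apparently protective heatwave effects as null;
  `allow_protective = TRUE` disables the floor.
* **Coefficient sampling scale.** Monte-Carlo draws are taken on the log-RR
  (β) scale, where the normal approximation for fitted coefficients lives;
  draws and ensemble members are concatenated into a single empirical
  distribution before taking percentiles.
* **Variability measure for uncertainty shares.** Variance of the
  window-average AN as each source (RR parameters, climate models,
  population scenarios) runs over its levels with the others pinned to
  central values (β̂, the ensemble-mean calendar, the medium-fertility
  population). One-at-a-time evaluation around the central point is
  order-independent by construction. Range would be an alternative measure;
  variance was chosen because it adds across independent sources.
* **Mixed-sign contribution shares.** When a factor opposes the total
  change (e.g. a declining population damping a climate-driven increase),
  percentages "of the total" exceed 100 and mislead. The package then
  reports each contribution relative to the sum of the *positive*
  contributions and flags the output (`convention = "of_positive_sum"`,
  attribute `mixed_sign`). When all contributions share the total's sign,
  shares are plain percentages of the total and sum to 100.
* **Stabilized-warming (1.5 °C analogue) pairing.** The stabilized climate
  is represented by the early-century window (2021–2040) of the
  lowest-trend scenario. To express "deaths in 2090 under stabilized
  warming", that climate is paired with end-of-century population and age
  structure via the factor-state evaluator; the pipeline reports this
  cross-window pairing, and the same machinery evaluates any other pairing.
* **Aging operationalization.** "Aging" is the vector of age-group shares
  (with age-specific mortality rates fixed inside the evaluator), and
  "size" is the total-population scalar, so size × shares reconstructs the
  age-specific populations and the three drivers are independently
  switchable — the property the permutation-average decomposition needs.
* **Frozen mortality rates.** Yearly baseline rates are held at their
  2010–2019 mean from 2020 onward, the usual stable-rates assumption for
  century-scale projection; rate change is deliberately *not* a
  decomposition factor.

## What the synthetic-data generator emulates

Real inputs of this kind (regional-climate-model output, vital statistics,
population projections) are not redistributable, so the package ships a
generator that reproduces the *statistical structure* the analysis relies
on:

* **Temperature** (`generate_temperature()`): per cell,
  base mean + annual sinusoid peaking July 15 + linear warming trend
  (°C/decade) + AR(1) noise (innovation SD σ, lag-1 correlation ρ), on a
  365-day no-leap calendar. Defaults σ = 2 °C, ρ = 0.7, seasonal amplitude
  10 °C are typical mid-latitude values: they give warm-season Tmax spreads
  of a few degrees and multi-day persistence of hot spells, which is what
  the run-length detector needs to be exercised on.
* **Grid** (`make_grid()`): a rectangular half-degree grid split into 2–7
  latitude-band climate zones with annual-mean Tmax decreasing poleward
  (default 10 × 10 cells, 4 zones; the demo pipeline uses 6 × 6 to keep the
  end-to-end run light).
* **Population** (`generate_population()`): a national total rising to a
  peak year then declining (Gaussian in time), fixed spatial weights, and
  an oldest-age share growing linearly at `aging_rate` per year at the
  youngest group's expense. Default scenarios peak in 2028/2032/2038 with
  peak ratios 1.08/1.15/1.25 for low/medium/high fertility, and
  `aging_rate = 0.002` (0.2 percentage points per year — the 75+ share
  roughly triples over the century, a realistic aging trajectory for a
  rapidly aging country). Age-specific yearly mortality rates (0.003 /
  0.020 / 0.080 for 0–64 / 65–74 / 75+) fluctuate mildly before 2020 and
  are frozen at their 2010s mean thereafter.
* **Daily deaths** (`generate_daily_mortality()`): Poisson counts with
  log-mean log(baseline) + β·HW + Σ coef·covariate, with known β per zone —
  the ground truth for the parameter-recovery tests.

What it does **not** emulate: spatially correlated weather across cells,
bias-correction artifacts, humidity or pollution interactions, migration,
harvesting/short-term mortality displacement, and adaptation. Passing tests
therefore demonstrate the correctness of the estimation machinery under the
model's own assumptions, not the realism of any particular projection for
real populations.

## Numerical choices and degenerate inputs

* Poisson fits use IRLS (`stats::glm`) at relative tolerance 1e-8; a
  constant heatwave indicator (complete separation of the two-group mean
  structure) is an explicit error rather than a divergent fit.
* The attributable-number equation is evaluated by exact joins; linearity
  in population, rate, heatwave days, and AF holds to machine precision and
  is asserted in the tests, as is additivity over cells and months.
* Decomposition exactness (contributions summing to the total change) holds
  to 1e-9 relative tolerance by telescoping.
* Window means require full coverage: a partial 20-year window is an error,
  not a silent average of fewer years.
* Empirical CI percentiles use quantile type 7, matching the threshold
  convention; with σ = 0 draws the interval collapses onto the point
  estimate exactly.
* All generators take explicit integer seeds; the pipeline fans a single
  root seed out to per-stage substreams, and reruns are bit-identical.

## Problem sizes

The shipped demo configuration runs a 6 × 6 grid over 1986–2100 with two
ensemble members, three emission scenarios (0.10 / 0.25 / 0.50 °C per
decade), three population scenarios, 12 site-level Poisson fits of 2,500
days each, and 1,000 Monte-Carlo coefficient samples — a deliberately
desk-scale configuration chosen so the complete pipeline, including
uncertainty decomposition, finishes in about a minute while every stage
still runs at realistic relative proportions. Unit and property tests use
single cells or 2 × 2 grids over a few years.

## Known limitations

* RRs are age-invariant by default; an age-stratified AF enters only if an
  age-specific RR table is supplied.
* The added-versus-main-effect distinction for heatwave mortality, lag
  structure, and distributed-lag nonlinear modelling are out of scope; the
  regression interface accepts arbitrary covariate columns instead of
  imposing a specific seasonality/confounder specification.
* Intensity-based heatwave metrics (amplitude, humidity-based indices,
  compound extremes) are not implemented; the detector is purely
  threshold/run-length based.
* The uncertainty-share decomposition ignores interactions between sources;
  shares are one-at-a-time variances normalized to 100%.
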