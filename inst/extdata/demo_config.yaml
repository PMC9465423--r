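# Demo configuration for the synthetic end-to-end pipeline.
# Values mirror default_config(); anything omitted falls back to it.
seed: 42
grid:
  nx: 6
  ny: 6
  lat0: 22.0
  lon0: 105.0
  spacing: 0.5
  n_zones: 4
  base_mean_south: 24.0
  lapse: 0.8
years: [1986, 2100]
ref_years: [1986, 2005]
percentile: 92.5
min_run: 3
season: [5, 9]
models: [m1, m2]
scenarios:
  low:  {trend: 0.10, sigma: 2.0, rho: 0.7, seasonal_amp: 10.0}
  mid:  {trend: 0.25, sigma: 2.0, rho: 0.7, seasonal_amp: 10.0}
  high: {trend: 0.50, sigma: 2.0, rho: 0.7, seasonal_amp: 10.0}
windows:
  baseline: [1986, 2005]
  y2030: [2021, 2040]
  y2060: [2051, 2070]
  y2090: [2081, 2100]
population:
  low:    {peak_year: 2028, peak_ratio: 1.08, aging_rate: 0.002}
  medium: {peak_year: 2032, peak_ratio: 1.15, aging_rate: 0.002}
  high:   {peak_year: 2038, peak_ratio: 1.25, aging_rate: 0.002}
rr:
  zone_logrr: {Z1: 0.05, Z2: 0.07, Z3: 0.09, Z4: 0.11}
  sites_per_zone: 3
  n_days: 2500
  hw_prob: 0.10
  baseline_rate: 30.0
  alpha_q: 0.05
mc:
  n_samples: 1000
  percentiles: [2.5, 97.5]
uncertainty:
  n_rr_levels: 50
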