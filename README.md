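# cpforager

Daily movement behaviour and breeding performance of a central-place
foraging raptor: a tested, reusable pipeline from raw GPS fixes to
random-intercept mixed models.

## The problem

Territorial raptors (large eagles and their kin) are central-place
foragers during the breeding season: daily movement radiates from and
returns to the nest. Long-term monitoring records each territorial
pair-year's staged breeding outcome — laid → hatched → fledged, with 0, 1
or 2 fledglings — while GPS tags on a subset of adults record where the
birds actually go. `cpforager` links the two data streams for anyone
analysing biologging + monitoring data of this design:

* **GPS pipeline** — quality control (Hdop > 10 or < 3 satellites
  removed, strict bounds; duplicate timestamps; implied-speed outliers),
  greedy thinning to a 15-min minimum interval, segmentation into local
  civil days (≥ 10 locations each), a sunrise anchoring rule
  ([−30, +120] min around NOAA-computed sunrise), and three daily
  metrics:
  * proportion of locations in flight, `k/n`, with flight = speed
    strictly above 3 m/s derived from consecutive displacements;
  * range of movement = median great-circle distance from each location
    to the day's first (anchor excluded from the median set);
  * straightness `D/L` = net displacement over path length, in [0, 1].
* **Environment** — 95% Gaussian-kernel home ranges on a local
  transverse-Mercator plane, joins of daily 8 × 8 km gridded weather to
  home ranges (unweighted cell averaging, area-weighted option), a 70 km²
  nest disc for untracked territories, and phase summaries (cumulative
  rain, min/max daily mean temperature, counts of days with wind
  > 7.5 m/s and < 2.5 m/s, strict).
* **Mixed-model engine** — Gaussian LMM by profiled maximum likelihood
  and binomial GLMM by 15-node adaptive Gauss–Hermite quadrature, both
  random-intercept; per-dataset covariate standardization
  `z = (x − x̄)/σ`; Wald inference with the p < .05 / p < .1 tagging
  convention; validated against brute-force integration, closed forms and
  `lme4`.
* **Analysis battery** — three breeding-stage GLMMs (laying, hatching,
  fledging on their staged subsets, recruitment 0/F/M/MF + preceding-phase
  weather, site intercept); per-sex × per-phase movement models (binomial
  flight, Gaussian log-range and logit-straightness, with experience,
  rain, temperature, wind + wind²); phase × sex comparisons; descriptive
  mean/SD/min/max/CV% tables; and per sex × phase × metric Gaussian LMMs
  of the fledgling count on phase-averaged movement.
* **Synthetic data** — a generator that emulates all inputs (weather,
  territories, tracks with planted QC violations, staged breeding
  outcomes) with known ground truth: daily flight probability is
  logit-linear in rain, temperature, experience and a quadratic wind
  response peaking at 5 m/s; laying probability by recruitment level is
  0.95 / 0.85 (M) / 0.71 (F) / 0.46 (MF); the male-rearing-flight effect
  on productivity is −0.26 per SD. Every downstream stage is tested by
  recovering these numbers.

The core statistical object is the random-intercept mixed model

  g(E[y_ij]) = x_ij' β + u_i,  u_i ~ N(0, σ_u²)

with g the identity (Gaussian) or logit link (binomial counts), fitted by
ML; for the binomial case the marginal likelihood ∫ Π_j p(y_ij | β, u) φ(u; 0, σ_u²) du
is integrated by adaptive Gauss–Hermite quadrature per group.

## Worked example

```r
library(cpforager)

# simulate a small tracked population (4 sites x 2 seasons)
cfg <- sim_config(n_sites = 4, n_years = 2, seed = 7)
ds  <- simulate_dataset(cfg)

# raw fixes -> QC -> daily movement metrics
metrics <- preprocess_tracks(ds$fixes)
head(metrics[c("individual_id", "date", "n_fixes", "k_flight",
               "prop_flight", "range_m", "straightness")], 3)
#>   individual_id       date n_fixes k_flight prop_flight   range_m straightness
#> 1         f0009 2019-12-01      45        9   0.2000000 2006.6352   0.03525471
#> 2         f0009 2019-12-02      42       10   0.2380952 4215.6472   0.19475444
#> 3         f0009 2019-12-03      28       10   0.3571429  987.4585   0.05687284

# join weather + experience, fit the daily flight model
daily <- join_daily_covariates(metrics, ds$individuals, ds$events, ds$nests,
                               ds$cells, ds$weather, ds$windows)
fit <- fit_binomial_glmm(
  cbind(k_flight, n_fixes - k_flight) ~ experience + rain + temp + wind + I(wind^2),
  daily, group = "individual_id")
wald_summary(fit)[, c("term", "estimate", "se", "p", "tag")]
#>          term estimate    se        p         tag
#> 1 (Intercept)   -2.068 0.095 3.1e-105 significant
#> 2  experience   -0.123 0.055  2.5e-02 significant
#> 3        rain   -1.363 0.049 1.1e-169 significant
#> 4        temp    0.096 0.012  1.8e-16 significant
#> 5        wind    3.509 0.074  0.0e+00 significant
#> 6   I(wind^2)   -4.639 0.102  0.0e+00 significant

coef_raw(fit)[["rain"]]   # -0.295  (generator truth -0.30, per mm of rain)
wind_vertex(fit)          #  5.05   (generator truth 5 m/s)
```

Slopes are standardized (comparable across terms); `coef_raw()` returns
raw covariate units and `wind_vertex()` the raw-scale wind optimum
−β_wind/(2β_wind²). Rainy days sharply reduce time in flight, flight
peaks at intermediate wind speeds (soaring conditions), and more
experienced birds fly less — exactly the structure the generator plants.

A one-shot run of the whole pipeline (simulate → preprocess → phase
weather via 70 km² nest discs → model batteries → CSVs + JSON manifest
with exact per-rule QC counts):

```r
run_pipeline(run_config(simulate = TRUE, sim_n_sites = 8, sim_n_years = 3,
                        seed = 1, out_dir = "out"))
```

or from a shell:

```sh
Rscript -e 'cpforager::cpf_cli()' preprocess --tracks tracks.csv --out daily_metrics.csv
Rscript -e 'cpforager::cpf_cli()' all --seed 1 --out_dir out
```

Key output columns: `daily_metrics.csv` (one row per individual-day:
n_fixes, k_flight, prop_flight, range_m, straightness, anchor_ok),
`phase_weather.csv` (site × year × phase: rain_cum_mm, temp_min_c,
temp_max_c, days_wind_above, days_wind_below), coefficient CSVs per
battery (term, estimate, se, z, p, ci_low, ci_high, tag) and
`predicted_laying.csv` (per-recruitment-level probability, at-mean-weather
and marginal).

## Documentation

`vignettes/methods.Rmd` describes the models and their assumptions, every
tunable threshold with units and defaults, what the synthetic generator
does and does not emulate, numerical choices, and known limitations.
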