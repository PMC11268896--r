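---
title: "Methods: from GPS fixes to breeding performance in a central-place forager"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from GPS fixes to breeding performance in a central-place forager}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpforager)
```

## The problem

Territorial raptors such as large eagles are central-place foragers during
the breeding season: every daily movement radiates from and returns to the
nest area. Their breeding performance is monitored at the pair-year level
(did the pair lay, hatch, fledge; how many chicks fledged), while GPS tags
on a subset of adults record daily movement. `cpforager` implements a
reusable pipeline that connects the two: it cleans raw GPS fixes, reduces
each tracked individual-day to three movement metrics, joins gridded daily
weather, and fits the random-intercept mixed models that relate weather and
individual experience to daily movement, and movement to productivity.

Because the motivating field data cannot be redistributed, the package
ships a synthetic-data generator that emulates every input — tracking,
weather, territories and staged breeding outcomes — with known ground
truth, so each stage is testable by parameter recovery.

## Daily movement metrics

A fix table (individual, UTC timestamp, WGS84 lat/lon, Hdop, satellite
count) passes through:

1. **Quality control** (`filter_quality()`): fixes with Hdop > 10 or fewer
   than 3 satellites are dropped (strict inequalities; missing quality
   metadata is retained and counted, since some tag brands omit the
   fields); exact duplicate timestamps are dropped (first kept); an
   implied-speed ceiling (default 40 m/s) drops the later fix of any
   impossible jump.
2. **Thinning** (`thin_min_interval()`): greedy retention to a minimum
   15-min gap, so heterogeneous duty cycles become comparable.
3. **Daily segmentation** (`build_daily_tracks()`): fixes are grouped by
   local civil date (fixed UTC+1 offset, configurable); days with fewer
   than 10 locations are dropped; the day's first fix is flagged as a valid
   anchor iff it falls within [sunrise − 30 min, sunrise + 120 min].
   Sunrise is computed from the NOAA low-order solar-position series
   (zenith 90.833°), accurate to a couple of minutes at mid latitudes.

Three metrics summarize each admitted day:

* **Proportion of locations in flight** `k/n`: a fix is in flight when its
  speed exceeds 3 m/s (strict). Speed is derived from consecutive
  displacements (great-circle distance over elapsed time); a fix takes the
  maximum of its two adjacent segment speeds, so a fix bounding a moving
  segment counts as moving. Mean-of-adjacent and forward-segment variants
  are available (`segment_speeds(method=)`).
* **Range of movement**: the median great-circle distance from each
  location to the day's first location (the nocturnal roost proxy). The
  anchor itself is excluded from the median set — including its zero
  distance would bias the range down — and the metric is absent (not zero)
  on days failing the sunrise-anchor rule. Even-length medians are the
  mean of the middle pair.
* **Straightness D/L**: net displacement between the first and last fix
  divided by the path length through all fixes, clamped to [0, 1]; a fully
  stationary day (L = 0) has no straightness.

Distances use the haversine formula on a sphere of radius 6371.0088 km. At
study-area scales (< 50 km) this is within 0.5% of an ellipsoidal geodesic
(verified against a Vincenty oracle in the tests), below GPS noise.

## Environment covariates

All planar geometry (kernel densities, areas, cell intersections) lives in
one local spherical transverse-Mercator projection centred on the data.
Daily weather comes on an 8 × 8 km cell grid (rain mm, mean temperature
°C, mean wind m/s).

* `kde_home_range()` estimates a fixed bivariate Gaussian kernel
  utilization distribution on a grid and takes the smallest-density
  contour holding 95% of the mass. Bandwidth is the bivariate normal
  reference rule per axis, `sd * n^(-1/6)`, with a scalar multiplier
  exposed; neither the bandwidth rule nor the grid is dictated by the
  motivating analysis, so both are configuration, not science.
* `daily_weather_for_region()` averages the cells intersecting a region —
  unweighted by default (the literal reading of averaging "the data
  available on the different cells"), with an overlap-area-weighted option.
* `nest_disc()` builds the 70 km² disc around a territory's nest centroid
  used when no tracked bird defines a home range (70 km² is the
  population's average breeding-season range).
* `phase_weather_summary()` reduces a phase window to the breeding-model
  covariates: cumulative rain, min and max of daily mean temperature, and
  counts of windy (> 7.5 m/s) and calm (< 2.5 m/s) days. The thresholds
  are strict: a day at exactly 7.5 or 2.5 m/s counts in neither bin (the
  bracketing is ambiguous in the source; strictness is symmetric and
  documented).

Phase windows default to: pre-breeding Dec 1 → laying (default Feb 28),
incubation 40 days (middle of the species' 37–41-day range), rearing 60
days (middle of 55–65); event-specific laying/hatching dates override the
defaults when known.

## The mixed-model engine

Every model in the battery is a random-intercept model — one grouping
factor, no random slopes — which keeps the marginal likelihood a
one-dimensional integral per group.

* **Gaussian LMM** (`fit_lmm()`): maximum likelihood via the closed-form
  profiled likelihood available for block covariance `σ_e²I + σ_u²J`;
  variance components are optimized on the log scale (REML optional; ML is
  the default so nested fixed-effect comparisons are coherent). Estimates
  below 1e−8 are reported as boundary-zero.
* **Binomial GLMM** (`fit_binomial_glmm()`): the random intercept is
  integrated out by adaptive Gauss–Hermite quadrature, 15 nodes by default
  (1 node = Laplace). Group modes come from a vectorized, step-halved
  Newton iteration; nodes are recentred and rescaled by the conditional
  curvature. The optimizer starts from the ordinary GLM fit with σ_u
  = 0.5, converging when the relative objective change is below 1e−13.
  The engine is validated three ways: against brute-force trapezoid
  integration of the marginal likelihood (`binomial_glmm_loglik()`, 1e−6),
  against closed-form reductions (σ_u = 0 equals ordinary logistic
  regression), and against an independent implementation (`lme4::glmer`,
  nAGQ = 15) on fixtures.
* **Inference** (`wald_summary()`): Wald normal z tests; p < .05 tagged
  `significant`, .05 ≤ p < .1 `marginal`, otherwise `ns`; 95% CIs as
  estimate ± 1.96·SE. No likelihood-ratio or degrees-of-freedom
  corrections — the battery reports slope CIs and p-values only.
* **Standardization**: continuous covariates are z-scored *within each
  model's dataset* (`standardize()`, sample SD), so slopes are comparable
  across terms; factor dummies and the intercept are untouched.
  `coef_raw()` inverts the scaling exactly, and `wind_vertex()` reports
  the raw-unit wind optimum −β₁/(2β₂) from a quadratic wind response.

## The analysis battery

* **Breeding models** (`fit_breeding_models()`): three binomial GLMMs with
  a site intercept — laying on all events, hatching on the laid subset,
  fledging on the hatched subset. Fixed effects: recruitment (treatment
  contrasts, reference "0" = no new recruit; levels absent from a subset
  are dropped with a warning) plus the standardized phase weather of the
  phase preceding each outcome. Two per-level probability columns are
  reported: the prediction at average weather, and the model-implied
  marginal probability (random intercept integrated out, averaged over the
  level's events). The latter is the unbiased estimand of the underlying
  level frequencies; the former carries a small Jensen gap whenever
  p ≠ 0.5, which matters when validating against generating values.
* **Movement models** (`fit_movement_models()`): per sex × phase, a
  binomial GLMM on (k flight, n − k not in flight), a Gaussian LMM on
  log range, and a Gaussian LMM on logit straightness, each with an
  individual intercept; covariates are experience, daily rain, daily mean
  temperature, wind and wind². The number of locations enters the range
  and straightness models only — it already defines the flight
  proportion's denominator. Straightness values of exactly 0 or 1 are
  nudged into [ε, 1 − ε], ε = 1e−3, before the logit.
* **Phase/sex comparison** (`phase_sex_comparison()`): each phase-averaged
  metric on sex × phase with an individual intercept, plus estimated cell
  means.
* **Descriptive table** (`descriptive_table()`): per sex × period ×
  metric: mean, sample SD, min, max and CV% = 100·SD/mean across
  individuals, computed from unrounded values (CV is undefined at mean 0).
  The "all periods" row averages each individual's phase means first; the
  aggregation is not dictated by the source and is stated here once.
* **Productivity models** (`fit_productivity_models()`): per sex × phase ×
  metric, a Gaussian LMM of the fledgling count (0/1/2) on the
  standardized phase-mean metric with a site intercept (a Gaussian rather
  than Poisson response, because counts capped at 2 under a Poisson model
  could predict impossible values). Only individuals tracked through a
  complete season (all three phases) enter. The random effect is a site
  intercept by convention with the breeding models; the source does not
  name it.

No multiple-testing correction is applied across the batteries — each
term's p-value is interpreted on its own, mirroring the analysis the
package reproduces.

## The synthetic world

The generator's defaults are the stated conditions of the emulated study,
chosen once:

* **Design**: one pair per site-year; experience 1–15 years, incrementing
  yearly and resetting to 1 on recruitment; recruitment category drawn per
  event with frequencies 0: 0.70, F: 0.12, M: 0.12, MF: 0.06 (the source
  does not print them; ~30% territory turnover is realistic for a
  long-lived raptor with high site fidelity).
* **Weather**: rain = wet-day Bernoulli (p = 0.25) × gamma (shape 0.8,
  scale 7.5 mm); wind gamma with mean 4.5 m/s; temperature = seasonal
  sinusoid (annual mean 12 °C, half-range 8 °C, coldest mid-January) +
  N(0, 2²) noise.
* **Daily behaviour**: logit flight probability = −0.7 + u − 0.30·rain +
  0.02·(temp − 12) − 0.12·(wind − 5)² − 0.05·(experience − 8), with an
  individual intercept u ~ N(0, 0.3²) drawn from a per-individual
  substream (stable across years). The wind optimum sits at 5 m/s, the
  empirical optimum for soaring flight in this system.
* **Fix-level structure**: ~40 fixes/day (shifted Poisson) at 15-min
  intervals, first fix at the nest near sunrise (uniform −30…+120 min;
  a configurable fraction of days violates the window on purpose), duty
  cycle capped before local midnight. The day's Binomial(n−1, p) flight
  fixes are laid out as contiguous runs of length ≥ 2, and the bird moves
  only on segments whose both endpoints are flight fixes, at
  3.5–8 m/s out-and-back along a per-day bearing through the nest
  (excursion radius 7.5 km). This construction makes displacement-based
  classification reproduce the truth labels exactly at zero GPS noise —
  the property the pipeline tests rely on — at the cost of not modelling
  within-interval tortuosity. A lone flight draw of k = 1 is rounded to 2
  or 0 with probability ½ to preserve the mean.
* **Breeding**: laying probability by recruitment level 0.95 / 0.85 (M) /
  0.71 (F) / 0.46 (MF); hatching 0.82 and fledging 0.90 base rates with
  max-temperature logit slopes −0.30; second chick with probability 0.57
  (so mean productivity ≈ 0.99). The male-rearing-flight effect on the
  count (−0.26 per SD) enters through one calibrated dial acting on the
  fledging logit and the second-chick probability; the dial is root-found
  at generation time so the implied population least-squares slope equals
  the configured value exactly — the clamped mechanism alone saturates
  near 0.25 and would otherwise attenuate it.
* **Planted QC violations**: configurable fractions of fixes with
  Hdop > 10 or < 3 satellites, of short days (< 10 fixes) and of
  anchor-window violations, so QC accounting is testable to exact counts.
* **Seeds**: one master seed; weather, population, per-individual tracks,
  breeding, tagging and individual intercepts each derive fixed-offset
  substreams, so adding an individual does not perturb the others.

What the generator does **not** emulate: within-interval flight
tortuosity (each 15-min displacement is straight), thermal/orographic
uplift, multi-day memory or site-fidelity learning, spatially correlated
weather between cells, tag-brand-specific error structure, and a survival
process. A green recovery test therefore establishes that the estimation
machinery is consistent for data with this covariate structure — not that
the field estimates themselves are reproduced.

## Numerical choices and degenerate inputs

* Great-circle distances everywhere; clamping of rounding artefacts at
  the asin boundary.
* Binomial AGQ mode search: Newton with per-group step-halving only for
  steps > 0.5 (the conditional objective is concave); mode tolerance
  1e−11; warm starts across likelihood evaluations.
* σ_u is optimized as log σ_u with a floor at 1e−8; fits at the floor are
  flagged boundary-zero and their σ_u row is dropped from the observed
  information before inversion.
* Complete separation is flagged (|β| > 15 or a singular information
  matrix) and `wald_summary()` refuses non-converged fits.
* Constant covariates, rank-deficient designs, k > n counts, unordered
  timestamps, zero elapsed time, missing weather records and unknown
  recruitment levels all raise errors naming the offending term, date or
  cell.
* `nlminb` reports of "singular convergence" (a flat profile at the σ_u
  boundary) are accepted as converged stationary points.

## Known limitations

* Daily models treat days within an individual as exchangeable given the
  random intercept; residual temporal autocorrelation is ignored (as in
  the analysis being reproduced) — SEs for slowly varying covariates may
  be slightly optimistic.
* The sunrise-anchor rule is applied only to the range metric by default
  (it is part of that metric's definition); a global flag exists.
* Daylight restriction of the flight proportion is available but off by
  default; solar-powered tags rarely record at night, so in practice all
  admitted fixes are daytime fixes.
* The KDE home range is a fixed-kernel estimator; no autocorrelation-aware
  utilization methods are provided.
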