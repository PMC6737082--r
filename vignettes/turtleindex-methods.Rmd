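---
title: "Methods: a relative-abundance index for oceanic-stage juvenile loggerheads from observer line transects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a relative-abundance index from observer line transects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Oceanic-stage juvenile sea turtles occur at very low densities over enormous
areas, so dedicated surveys are rarely feasible. Fishery observer programmes
offer an alternative: observers on fishing vessels run short, standardized
visual strip transects (here, 15-minute transects up to six times a day)
whenever the vessel is travelling. The price of this opportunistic effort is
the absence of a survey design: coverage follows the fleet, detectability
varies with sea state, observers differ, measurements are heaped, and almost
all transects record zero turtles. `turtleindex` turns such data into an
annual relative-abundance index with bootstrap uncertainty, and relates that
index to an external annual nest-count series at a range of lags.

The pipeline has five stages, each exposed as ordinary functions:

1. **QC** (`qc_pipeline()`): length/speed plausibility, sea-state cut,
   kernel-density spatial core.
2. **Detection** (`bin_sightings()`, `fit_detection()`): smearing of heaped
   measurements, perpendicular distances, truncation, binned
   maximum-likelihood detection functions with AIC selection.
3. **Count model** (`fit_zipgam()`, `backward_select()`, `annual_index()`):
   a zero-inflated Poisson GAM with a log effective-area offset.
4. **Uncertainty** (`bootstrap_pipeline()`): per-year resampling with full
   two-stage refitting.
5. **Trend** (`cross_correlation()`): lagged Pearson correlation against a
   nest-count series.

## Quality control

Transects are filtered in a fixed order; each step only removes records.

* **Length.** A 15-minute transect whose geodesic start-end distance lies
  outside [1.35, 5.40] km implies an implausible average speed (outside
  [5.40, 21.60] km/h) or a strongly curved track; both bounds are treated as
  *inclusive* so that the printed speed bounds remain attainable.
* **Sea state.** Transects above Beaufort 3 are discarded; sightability of
  a small turtle at the surface collapses in white-capped seas.
* **Spatial core.** Transect midpoints are projected to a local Lambert
  cylindrical equal-area plane (km), a bivariate Gaussian kernel density is
  evaluated on a 512 x 512 grid with the normal-scale ("reference")
  bandwidth per axis, `sd * n^(-1/6)`, and the density threshold enclosing
  95% of the estimated probability mass defines the core; transects whose
  midpoint falls below the threshold are spatial outliers. The enclosed
  mass is accurate to about +/- 0.01 at this grid resolution, which is the
  tolerance the tests use. Degenerate (zero-variance) point sets are
  rejected.

## Detection probability

Observers record radial distance `r` (visually estimated) and sighting angle
`theta`; the perpendicular distance is `d = r sin(theta)`, with angles beyond
90 degrees folding symmetrically because sightings on either side of the
vessel are analysed together.

Visually estimated measurements heap on favoured values (10-degree and
10-metre spikes). Each recorded sighting is therefore *smeared* uniformly
over the sector `(theta - phi, theta + phi) x (r(1-s), r(1+s))` with
defaults `phi = 5` degrees and `s = 0.2`. `s` is a *proportion* of the
recorded distance: the sector definition `r(1 +/- s)` admits no other
reading. The default mode integrates the induced perpendicular-distance
distribution on a fixed 41 x 41 quadrature grid and allocates fractional
weights to the distance bins (0-5, 5-10, 10-20, 20-30, 30-40, 40-50,
50-100 m); a stochastic single-draw mode exists for comparison with
software that realizes one draw per sighting. Weights conserve group size
before truncation; smeared mass beyond the 100 m truncation distance is
discarded and reported, never renormalized. A sector reaching below 0
degrees is clipped at 0.

Detection keys are the hazard-rate `g(d) = 1 - exp(-(d/sigma)^-b)` and the
half-normal `g(d) = exp(-d^2 / 2 sigma^2)`, optionally multiplied by cosine
(`cos(k pi d/w)`, k >= 2) or simple polynomial (`(d/w)^(2k)`, k >= 2)
adjustments renormalized so `g(0) = 1`. Covariates (Beaufort sea state by
default; glare and vessel speed are available) act on the scale:
`log sigma = X beta`, with the hazard-rate shape `b` shared across strata —
the standard multiple-covariate convention. Fitting maximizes the binned
conditional-on-detection multinomial likelihood (cell probability
proportional to the integral of `g` over the bin, 24-node Gauss-Legendre per
bin), supports fractional weights, and selects among candidates by
`AIC = 2k - 2l` with ties broken toward fewer parameters. Fits whose `g` is
not monotone non-increasing on `[0, w]` are rejected. The average
detectability `p = (1/w) integral g` is computed by adaptive quadrature per
stratum, and a Pearson chi-square with `df = bins - k - 1` summarizes
goodness of fit.

## The count model

Counts per transect are modelled as zero-inflated Poisson:

* Poisson mean `lambda_i = A_i exp(eta_i)`, with `A_i` the *effective area*
  `length x strip width x p` (km^2) entering as a log offset;
* `eta = X beta + f(dcoast) + Z u`, with year, Beaufort and time-of-day
  (morning 09-11 h, midday 13-15 h, afternoon 17-19 h) as factors, SST
  linear, `f` a penalized cubic regression spline of distance to coast
  (basis size k = 8, second-derivative penalty, basis built by
  `mgcv::smoothCon()`), and `u` ridge-penalized i.i.d. observer effects;
* structural-zero probability `pi = 1 - logistic(gamma0 + gamma1 eta)`,
  tying zero inflation to the same linear predictor (the one-stage
  formulation). `gamma1` is kept in (0, 5) through a logistic
  reparameterization: unbounded, the slope admits a degenerate
  separation-type optimum in which tiny shifts of `eta` switch `pi` between
  0 and 1; positivity encodes that zero inflation decreases where expected
  density is high. A constant-`pi` fallback (`zi = "constant"`) and a pure
  Poisson variant (`zi = "none"`) are provided.

Estimation maximizes the penalized log-likelihood by BFGS with an analytic
gradient; objective and gradient share one cached evaluation per parameter
vector. The smoothing parameter and the observer ridge are chosen on outer
log-spaced grids (7 and 5 points) minimizing the conditional AIC
`2 edf - 2 l`, where `edf = tr[(H + P)^{-1} H] + dim(gamma)` and `H` is the
Gauss-Newton-style curvature `C' W C` with per-observation weights obtained
by differencing the analytic eta-score (clamped at zero where the
likelihood is locally non-concave). Backward selection repeatedly removes
the term whose deletion most decreases conditional AIC (the year term,
which carries the index, is protected by default) and records a path with
likelihood-ratio chi-square p-values; the path is monotone non-increasing
in AIC by construction. Numeric linear terms are screened for pairwise
collinearity first (|r| > 0.7 drops the later-listed member — in the
synthetic data this removes NPP, which is fabricated collinear with SST).

Two numerical facts shape interpretation. First, `pi` and `lambda` are only
*jointly* identifiable when the Poisson mean is appreciable: as
`lambda -> 0` the profile likelihood in `pi` flattens, so at realistic
encounter rates (~2% of transects nonzero) the split between structural and
sampling zeros is weakly determined. The product `(1 - pi) lambda` — the
expected count, which is all the index uses — remains well identified, and
the package's tests check `pi` recovery at a dense design point where it is
identifiable. Second, the deviance scale uses the saturated ZIP
log-likelihood (zero observations contribute probability one), so explained
deviance on sparse synthetic data is small even when year effects are well
estimated; it is reported for completeness, not used for selection.

The **annual index** standardizes prediction over the pooled all-years
covariate distribution: every transect in the reference grid is assigned
each year in turn, `E[y]/A = (1 - pi) exp(eta)` is averaged over the grid,
and the mean is scaled to individuals per 0.1 km^2. Standardizing on a
common grid removes year-by-covariate sampling imbalance, which is the
point of the model-based approach. If the fitting offsets were expressed in
an area unit other than km^2, `offset_unit_km2` declares it, making the
reported index invariant to the unit choice; with the unit fixed, doubling
every effective area halves every index, as an offset must.

## Bootstrap uncertainty

Both estimation stages are refitted on each of `n_reps` (default 1000)
datasets resampled with replacement *independently within each year*
(per-year sample sizes are preserved exactly; sightings travel with their
transect; resampled copies get fresh ids). The selected model structure —
detection key, adjustment, covariates, count-model terms, and the smoothing
and ridge penalties — is held fixed; only parameters are re-estimated.
Refitting the structure too would be a different (and much more expensive)
estimator of model-selection uncertainty; holding it fixed is the
conventional reading of a two-stage refit. Replicates that fail to converge
are dropped and counted (warning above 10% failures, error above 50%). The
per-year standard deviation over replicates is the bootstrap standard error
(BSE) and the 2.5th/97.5th percentiles form the 95% interval (BCI) —
percentile rather than BCa, making no distributional assumption. A master
seed spawns one child seed per replicate, so results are independent of
execution order.

## Lagged cross-correlation

For each lag `l` in 0..12, the index at year `t` is paired with nest counts
at year `t - l` (positive lag: nests lead) and the plain Pearson correlation
over the overlapping pairs is computed — deliberately *not* the
global-mean/variance normalization of a classical ccf, matching the
lag-plot convention; the two differ for short series. Lags with fewer than
four overlapping pairs are reported as missing, never as zero. The module
reports correlations only: tracking of a lagged nest series is consistent
with recruitment driven by nest production, but the correlation itself
establishes no causal relationship.

## The synthetic-data generator

`simulate_fleet()` is first-class, tested code that emulates the statistical
structure the analysis assumes, with truth carried alongside for
parameter-recovery tests:

* ~1184 transects/year over 15 years from 2001, positions drawn around five
  fabricated fishing-ground clusters with ~5% uniform spatial outliers;
  ~10% of lengths planted outside [1.35, 5.40] km; Beaufort 0-5 with ~15%
  above 3 — each planted violation class exercises one QC filter;
* true annual density proportional to a built-in synthetic nest series
  lagged by 3 years (the series is fabricated with a pronounced ~43%
  decline into 2006 and a recovery, the shape the index should track),
  scaled so the mean density is `base_density` = 0.4 turtles/km^2;
* counts zero-inflated Poisson (`zero_inflation` = 0.4) with log-normal
  observer effects (SD 0.3), a smooth distance-to-coast suppression within
  ~10 km of the coast, and a weak negative SST effect; together with
  hazard-rate detection thinning (`sigma0` = 20 m at Beaufort 0, shape
  `b` = 3, scale factor 0.64 per Beaufort step) these defaults reproduce
  the study conditions of ~2% nonzero transects and per-Beaufort average
  detectabilities ordered from roughly 0.27 (Beaufort 0) down to ~0.11
  (Beaufort 2-3);
* turtles are placed uniformly in perpendicular distance out to 300 m
  (beyond the 100 m analysis truncation on purpose), angles are uniform on
  (0, 180) with the side ignored (perpendicular distance is
  side-symmetric), and recorded measurements are heaped to the nearest 10
  degrees / 10 m; a heaped distance that would round to 0 m is recorded at
  10 m so recorded radial distances stay positive;
* group size is a knob (mean 1.05) that is *unvalidated*: no field
  group-size distribution was available, so sizes are 1 + Poisson(0.05);
* one RNG sub-stream per survey year, derived from the configuration seed,
  keeps datasets byte-identical under a fixed seed.

What the generator does **not** emulate: real oceanography (no currents, no
satellite fields — environmental covariates are smooth fabricated fields),
vessel movement, group-size biology, availability bias from diving, or
spatial autocorrelation of sightings beyond the fabricated covariate
fields. Passing recovery tests therefore demonstrates the estimator's
correctness under its own assumptions, not robustness to violations real
observer data may exhibit.

## Problem sizes used by the test suite

Simulation studies in the tests use sizes chosen to give stable Monte-Carlo
conclusions at practical cost; all are the package's own choices and are
stated here so they can be reproduced:

* detection recovery: 100 seeds x 500 binned detections (truth sigma = 30 m,
  b = 3, no heaping); median recovery within 15% (scale) and 25% (shape);
* index recovery: one default-size fleet (15 years, ~17k transects);
  note that at the default ~2% encounter rate (~25 positive transects per
  year) the Poisson noise floor alone limits the correlation between
  estimated and true annual densities to a median of about 0.68 — an ideal
  estimator does no better — so near-unity recovery is attainable only at
  elevated encounter rates;
* bootstrap coverage: 50 datasets x 200 replicates at ~2000 transects
  (5 years x 400), with detection scale constant across sea states and
  nuisance effects disabled so the estimand `0.1 (1 - pi) density` is
  exact;
* lag recovery: 50 seeds of a strong-signal fleet (500 transects/year,
  base density 5 turtles/km^2, ~120 positive transects per year), where
  adjacent lags are statistically distinguishable;
* KDE calibration: 10,000-point Gaussian clouds, tolerance +/- 0.01 of the
  requested mass.

## Known limitations

* The detection stage treats sightings as independent and group size as
  exact; no availability-bias correction is attempted, so the index is
  relative, not absolute.
* The zero-inflation split is weakly identified at sparse encounter rates
  (see above); only `(1 - pi) lambda` should be interpreted.
* The equal-area projection is local; the pipeline is not meant for study
  regions spanning tens of degrees of latitude.
* Percentile BCIs undercover slightly when replicate distributions are
  strongly skewed and the per-year positive count is very small.
* The collinearity screen is pairwise only; near-multicollinearity among
  three or more covariates passes it.
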