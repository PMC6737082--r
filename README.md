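# turtleindex

Annual relative-abundance indices for oceanic-stage juvenile loggerhead sea
turtles (*Caretta caretta*) from opportunistic fishery-observer line
transects, with bootstrap uncertainty and lagged comparison against
nest-count series from the source rookeries.

## The problem and who this is for

After hatching on beaches in the southeastern United States, loggerheads
spend roughly a decade in the open North Atlantic, where their abundance is
essentially unmonitored: population assessment leans on nest counts, which
only reflect juvenile mortality decades later. Observers on pole-and-line
tuna vessels run standardized 15-minute visual transects that, accumulated
over years, can support an index of in-water abundance — if the analysis
deals with the lack of survey design: coverage driven by the fleet,
sea-state-dependent detectability, heaped distance/angle estimates, ~98%
zero counts, and observer-to-observer variation. This package implements
that analysis for quantitative ecologists working with observer-programme
sighting data, together with a synthetic-data generator so every stage is
testable without access to any observer database.

## The method

1. **QC filtering** — transects kept when the geodesic start–end length is
   in [1.35, 5.40] km (15-minute speeds of 5.40–21.60 km/h), Beaufort ≤ 3,
   and the midpoint lies inside the 95% contour of a reference-bandwidth
   kernel density of all midpoints (equal-area projection).
2. **Detection function** — heaped measurements are smeared uniformly over
   the sector (θ ± φ) × (r(1 ± s)) with φ = 5°, s = 0.2; perpendicular
   distances d = r sin θ are truncated at w = 100 m (two-sided strip width
   200 m) and grouped into bins (0–5, 5–10, 10–20, 20–30, 30–40, 40–50,
   50–100 m). Hazard-rate g(d) = 1 − exp(−(d/σ)^−b) and half-normal
   g(d) = exp(−d²/2σ²) keys, with cosine/polynomial adjustments and
   covariates on the scale (log σ = Xβ; Beaufort by default), are fitted by
   binned multinomial maximum likelihood and selected by AIC, with a χ²
   goodness-of-fit test.
3. **Count model** — counts are zero-inflated Poisson with
   λ = A·exp(η), offset log A = log(length × strip width × p̂) (effective
   area, km²), η containing year/Beaufort/time-of-day factors, linear SST,
   a penalized cubic regression spline of distance to coast, and ridge
   penalized observer effects; P(structural zero) = 1 − logistic(γ₀ + γ₁η).
   Penalized-likelihood fitting, conditional-AIC smoothing selection, and
   backward term selection. The annual index is the standardized prediction
   E[y]/A = (1 − π)exp(η) averaged over the pooled covariate grid, in
   individuals per 0.1 km².
4. **Bootstrap** — transects resampled with replacement independently within
   each year; both stages refitted (structure fixed) per replicate; BSE and
   percentile 95% BCIs.
5. **Trend** — Pearson correlation between index(t) and nests(t − lag) for
   lags 0–12 (positive lag: nests lead).

See `vignette("turtleindex-methods")` for assumptions, tunable parameters,
numerical choices and limitations.

## Worked example

Simulate a five-year observer programme (elevated density so the example is
quick and clearly patterned), run the pipeline, and correlate the index
with the generator's nest series:

```r
library(turtleindex)

cfg <- sim_config(n_years = 5, transects_per_year_mean = 600,
                  base_density = 2, seed = 42)
fleet <- simulate_fleet(cfg)

qc <- qc_pipeline(fleet$transects, fleet$sightings)
qc$report
#> Transect QC report
#>   input                : 3026 transects
#>   after length filter  : 2720 (-306)
#>   after Beaufort filter: 2318 (-402)
#>   after KDE core       : 2227 (-91)
#>   95% core area        : 181376 km^2
#>   sightings kept       : 309 of 382

binned <- bin_sightings(qc$sightings, qc$transects)
det <- fit_detection(binned)
det
#> Detection function: hazard_rate key, none adjustment, covariates: beaufort
#>   shape b = 3.133
#>   truncation 100 m, AIC 1031.21, average p = 0.198
#>   p by stratum:
#>     0     1     2     3
#> 0.254 0.174 0.149 0.122

p_hat <- predict_p(det, qc$transects)
off <- log(effective_area(qc$transects$length_km, 0.2, p_hat))
fit <- fit_zipgam(qc$transects,
                  model_spec(terms = c("year", "beaufort", "sst"),
                             zi = "constant"), off)
annual_index(fit)
#>   year  index se_log
#> 1 2001 0.1121 0.1356
#> 2 2002 0.1184 0.1256
#> 3 2003 0.1258 0.1303
#> 4 2004 0.0824 0.1540
#> 5 2005 0.0781 0.1581

idx <- annual_index(fit)
cross_correlation(annual_series(idx$year, idx$index),
                  annual_series(cfg$nest_series$year,
                                cfg$nest_series$nest_count), max_lag = 4)
#> Cross-correlation by lag (nests lead the index)
#>  lag     r n
#>    0 0.814 5
#>    1 0.707 5
#>    2 0.762 5
#>    3 0.937 5
#>    4 0.214 5
#> best lag: 3 year(s)
```

Reading the output: the three QC steps drop implausible lengths, rough seas
and spatial outliers in that order; detection selects the hazard-rate key
with Beaufort on the scale, average detectability p̂ ≈ 0.20 falling from
0.254 (calm) to 0.122 (Beaufort 3); the annual index is in individuals per
0.1 km² of effective area; and the index correlates most strongly
(r = 0.94) with the nest series lagged by the three years the generator
planted. `bootstrap_pipeline()` adds BSE/BCI columns, and `run_all()`
executes everything from CSV inputs to artifact files.

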