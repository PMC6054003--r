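---
title: "Methods: high-impact spot mapping for drybean under climate change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-impact spot mapping for drybean under climate change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beanhis)
```

## Scope and model chain

`beanhis` maps where projected climate change produces outlying yield
losses (or gains) for drybean across a region, at the resolution of a
monthly climatology grid. The chain is: coarse monthly climate-model
anomalies → delta downscaling onto a fine baseline climatology →
per-pixel stochastic daily weather → seasonal yield simulation under a
management factorial → spatial scaling and classification of the yield
change → site selection and ensemble uncertainty. Each stage is exposed
as ordinary functions on small S3 containers (`grid_raster`,
`monthly_climate`, `daily_weather`, `spot_classification`, ...), and
`run_pipeline()` chains them.

Two things the package deliberately does **not** do: it does not
re-implement a process crop model (the yield emulator is a simplified
water-/temperature-limited stand-in with the same interface a process
model would use), and it does not reproject rasters (all grids are
geographic lat/lon with square cells, cell-centre registered, rows
north→south). Raster I/O is plain-text ESRI ASCII grid plus CSV point
tables.

## Delta downscaling

A future scenario climate is `baseline + interpolated anomaly`. Anomaly
layers are interpolated bilinearly, treating coarse cell centres as nodes
and replicating edge values beyond the outermost centres; bilinear
weights are non-negative, so downscaling is monotone in the anomalies.
Temperature anomalies are additive (°C). Precipitation anomalies are
additive (mm) with a floor at zero; a multiplicative mode
(`mult_precip = TRUE`, delta read as a fraction of baseline) is available
because the additive/multiplicative choice is a genuine interpretation
point for precipitation — additive is the default since the delta method
is defined by *summing* interpolated anomalies. The interpolation scheme
itself (bilinear rather than spline/kriging) is an assumption; on smooth
anomaly fields, aggregating the downscaled deltas back to the coarse grid
recovers the coarse values to within edge-replication error (asserted in
the test suite).

## Stochastic weather generator

The generator is calibrated independently per pixel from the 12 monthly
values of precipitation, tmin and tmax; calibration is deterministic.

**Occurrence.** Wet/dry follows an order-*k* Markov chain, *k* ∈ {1,2,3}
(default 3). Writing *p* for the month's wet-day probability and
*h₁…h_k* for the previous days' wet indicators (most recent first), the
conditional wet probability is

  P(wet | h) = p·(1 − r) + r·Σᵢ wᵢhᵢ,   wᵢ ∝ 0.5^(i−1),

with persistence *r* ∈ [0, 1) (default 0.3). Because the blend is linear
in the history and the weights sum to one, the stationary wet-day
frequency is exactly *p* for any order — the chain adds persistence
(clustered wet spells, as tropical convection produces) without biasing
monthly totals. With *r* = 0 the chain degenerates to independent days
regardless of order, which the test suite checks through wet-run-length
statistics.

**Expected wet days.** Monthly climatologies carry totals, not wet-day
counts, so expected wet days are linked to the monthly total *P* by
`wet_days = a·P^b` (defaults a = 0.7, b = 0.55, capped at the days in the
month). The power link reflects the common empirical shape — wet-day
counts grow sublinearly with totals — and both coefficients are
arguments.

**Amounts.** Wet-day rain is gamma with fixed shape (default 0.8, a
right-skewed daily-rain shape) and a month-specific scale chosen so that
`days × p × shape × scale` equals the monthly total exactly. A 500-year
recovery test confirms monthly totals and first-order transition
frequencies within three standard errors.

**Temperature and radiation.** Daily tmax/tmin are normal deviates
(SD 1.2 °C, shared deviate with a 0.8 damping on tmin so the diurnal
range varies) about monthly means interpolated linearly between month
midpoints, with a 1 °C wet-day depression of tmax and a hard
`tmax ≥ tmin + 0.1` guard. Radiation is the FAO-56 extraterrestrial
envelope for the pixel's latitude times a dry/wet transmissivity
(0.70/0.45). Years are 365 days (no leap days), matching the DSSAT
weather-file convention of the bundled `.WTH` writer.

## Yield emulator and management protocol

The emulator enforces the management protocol of the study design while
keeping the physiology minimal:

* **Factorial.** `treatment_design()` enumerates 2 cultivars
  (ICTA OSTUA, BAT1289) × 2 generic soils (medium silty loam, medium
  sandy loam) × 2 fertilizer levels (F1: 64 kg/ha 12-30-06, F2: 128 kg/ha
  18-46-00, both side-dressed 30 kg N/ha at 22 days) = 8 treatments.
* **Soil bucket.** One 300-mm layer per soil, bounded by the −1.5 MPa
  lower limit and the drained upper limit. Daily: infiltrate
  `rain × (1 − runoff)`, cap at DUL, remove actual ET =
  `demand × min(1, ASW/0.5)` where ASW is the available-water fraction.
  Demand is a Hargreaves-type reference ET from temperature and
  radiation, times a crop coefficient (0.3 bare soil; 0.4/1.05/0.7 over
  the first 20 %, middle 60 %, last 20 % of the season).
* **Sowing.** The balance starts at the lower limit 60 days before the
  window opens (wrapping circularly within the replicate year, keeping
  years independent) and sowing is the first window day with ASW ≥ 50 %.
  Windows: primera 15 Apr–30 Jun, postrera 20 Aug–30 Sep, apante
  25 Oct–5 Dec.
* **Yield.** `potential × fert × mean(water factor) × mean(temperature
  factor)` over the cultivar's duration. The temperature factor is a
  trapezoid on daily mean temperature over cardinal temperatures
  8/20/28/35 °C with an extra linear penalty of 0.1 per °C of daily tmax
  above 35 °C — heat at the top of the range is the binding constraint
  for Mesoamerican drybean, and this term is what converts uniform
  warming into spatially structured losses. Fertilizer multipliers
  default to none 0.34, F1 0.7, F2 1.0 (unfertilized yields roughly a
  third of the high-fertilizer yields); with no nutrient process model
  the response is exactly multiplicative, so the site-level
  fertilizer-response ratio returns the configured ratio wherever yields
  are positive.

Absolute yields from the emulator are not meaningful beyond order of
magnitude; all downstream statistics are differences, scaled deviations,
ratios or directions, which is what the emulator is built to rank
correctly (monotone in water, decreasing above the temperature optimum,
ordered in fertilizer — all property-tested).

## Scaling and classification

The change field (future − baseline, mean of the 8 treatments) is scaled
to z-values by one of two methods, selectable because the underlying
methodology is describable either way:

* **Robust RMS** (default): iterate { centre on the mean of included
  points; scale = RMS of included deviations; exclude |dev| > 3·scale }
  until stable (≤ 20 passes), then scale *all* pixels by the final
  centre/scale. The multiplier 3 and the iteration cap are arguments. In
  small samples the exclusion rule cannot fire (max |z| is √(n−1)), which
  is expected behaviour, not a defect.
* **Getis–Ord Gi\***: the standardised local statistic with binary
  weights within a distance band (default 15 km), self included.
  A spatially constant field has a zero denominator; those cells return
  z = 0.

Categories: hotspot z ≤ −2, adaptation −2 < z ≤ −1, pressure z ≥ +1,
inclusive at the boundaries. On a standard normal field these cutoffs
reproduce the 68 %/95 % two-sided coverages, which the acceptance tests
verify on 10⁶ draws. Hotspots/adaptation spots are gated by the atlas
mask; pressure spots are mapped everywhere. The classification is
invariant to adding a constant to all yields (location-scale
standardisation), also property-tested.

Site selection applies the triple filter — within 15 km of a community,
inside the atlas, within ±100 m of the community's elevation — to
communities whose own cell is classified hotspot/adaptation. When no
community qualifies (weak-signal runs), the most negative-z communities
are used instead so that the site-level uncertainty stage still
executes; the fallback is flagged in the returned site table.

## Ensemble uncertainty

Across per-GCM change fields: mean, sample SD (n−1), and agreement
`100 × max(#negative, #non-negative)/n` with zero counted non-negative
(ties have no natural direction; the majority convention bounds agreement
below by 50 %). The zonal season summary reports count-based (not
area-weighted) percentages of zones with mean loss beyond a threshold
(default 10 %), over all zones and over the top-producing zones that
jointly hold ≥ 50 % of baseline production (greedy prefix after sorting
by production).

Note the pipeline computes the regional map from the *ensemble-mean
climate* (one crop run) but the site-level uncertainty from *per-GCM
runs*; the two are intentionally separate quantities and are never
asserted equal — they coincide only in a linear-response regime.

## Synthetic study region

The generator emulates the statistical structure the analysis needs, not
real geography:

* smooth DEM spanning 0–2200 m (the 400–2000 m drybean belt well
  covered), built from bilinearly upsampled coarse Gaussian noise plus a
  light box blur;
* bimodal May–October wet season (about 1400 mm/yr by default) with a
  July–August canicula dip (depth 0.5), spatially modulated by a smooth
  wetness field and a weak orographic term;
* temperatures lapsing 0.6 °C/100 m from a lowland base of
  tmax 35 / tmin 22 °C. The lowland tmax default sits at the cultivar
  cardinal maximum on purpose: it encodes the study premise that lowland
  pixels already touch the heat limit, so a +2 °C ensemble pushes them
  over it and the loss signal concentrates at low elevation;
* 19 pseudo-GCM coarse anomaly stacks per period, warming centres
  +1.0 °C (2020s) / +2.0 °C (2050s) with 0.4 °C inter-GCM spread and
  mixed-sign precipitation deltas (SD 10 % of monthly totals). Every
  inter-GCM difference scales with the spread parameters, so zero spread
  collapses the ensemble;
* a patchy mid-elevation growing-area mask and 15 communities sampled
  inside it.

What passing tests on this fixture do **not** show: skill on real
climates (no ENSO-like interannual structure, no orographic rain shadows,
no real GCM covariance), realism of absolute yields, or transferability
of the fertilizer multipliers. The fixture is built to exercise the
pipeline's contracts and direction logic, and the direction property —
hotspots concentrate in hot lowlands with negative mean change under a
+2 °C ensemble — is exactly what the end-to-end test asserts.

## Numerical choices and degenerate inputs

* Aggregation of non-divisible grids averages trailing partial blocks
  over available cells; all-missing blocks stay missing.
* Haversine distances use a 6371-km sphere (via `geosphere`).
* Robust scaling refuses all-equal inputs (zero scale) rather than
  returning infinities; Gi* returns 0 on constant fields.
* Per-pixel generator seeds derive from the master seed as
  `(seed × 7919 + cell index) mod (2³¹ − 1)`, keeping every run
  reproducible from one integer while decorrelating pixels.
* Elevation/distance filters are inclusive at their bounds (≤ 15 km,
  ≤ 100 m), matching the threshold conventions used throughout.

## Problem sizes

The shipped demonstrations and checks use a 40 × 40 fine grid (coarse
anomalies 8 × 8), 19 pseudo-GCMs and 20 replicate weather years — a scale
chosen so a full end-to-end run completes in about two minutes on a
single core while every statistic downstream of the weather generator
still has enough replication to be stable. The generator default of 99
replicate years remains the production setting for real analyses.

## Known limitations

The emulator has no phenology, nitrogen/phosphorus dynamics, CO₂
response, or pest/disease losses; fertilizer response is exactly
multiplicative by construction. Precipitation anomaly interpolation is
bilinear only. Zonal summaries are count-based. Only geographic lat/lon
grids are supported, and multi-layer NetCDF/GeoTIFF I/O is out of scope
for this build — grids move as ESRI ASCII text.
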