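---
title: "Methods: migration phenology and movement analysis in vegamove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: migration phenology and movement analysis in vegamove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

vegamove analyses multi-year GPS tracks of long-distance migrant gulls
moving between temperate East Asian wintering grounds and Arctic Siberian
breeding grounds. This vignette documents the models and procedures, the
parameters that matter and their defaults, the numerical choices, what the
synthetic generator does and does not emulate, and the package's known
limitations.

## Data model and conventions

The atomic input is a *fix table*: one row per GPS position with
`bird_id`, `timestamp` (POSIXct, stored in UTC), `lat`, `lon`, optional
`altitude_m` and `voltage_v`. All calendar-day logic — daily distance
sums, monitored spans, bout months, season bands — uses **UTC+9** days
(`Etc/GMT-9`), the civil time of the wintering range where deployments are
anchored.

A bird's *monitored span* in days is the last fix date minus the first fix
date. This exclusive-difference convention reproduces the packaged
reference table (a 25 Feb → 26 Oct track spans 243 days), and it is the
denominator of "mean distance travelled per day". Printed integer means in
cohort summaries use half-away-from-zero rounding, again matching the
reference table (3357.75 → 3358).

All spherical geometry uses the IUGG mean Earth radius 6371.0088 km.
Distances are haversine great-circle distances (via geosphere); mean
positions are normalized 3-D unit-vector means, which behave correctly for
Chukotka clusters straddling the antimeridian. Nothing in the package does
longitude arithmetic directly on degrees.

## Fix filtering and cohort bookkeeping

Failed location attempts are fixes with latitude and longitude both
exactly 0; duplicates are repeated (bird, timestamp) keys, keeping the
first. Identical *coordinates* at different times are retained — a
roosting gull genuinely repeats its position, and time-keyed duplicates
are the standard logger upload artifact. `filter_fixes()` is idempotent
and reports per-bird removal counts by reason.

Birds monitored under 100 days (`min_days`, configurable) are excluded as
too short to document seasonal movements. End-of-monitoring fates follow a
small decision tree: a stationary terminal window (all fixes in the final
5 days within 0.5 km — the radius is a tag-accuracy-scale default, not a
published value, and is configurable) indicates death or tag loss;
positions collected ≤ 80 % of the duty-cycle expectation and/or a last
voltage ≤ 3.9 V indicate technical failure; birds still transmitting at a
supplied study end date are censored alive; everything else is unknown.
Missing voltage skips that criterion and says so in the evidence string.

The per-bird summary's `longest_gc_km` is the maximum great-circle
distance between any summer-band fix (7 Jun–31 Aug) and any winter-band
fix (18 Dec–12 Apr), by exhaustive chunked scan. The packaged reference
table also prints a total-distance text range elsewhere quoted as
6531–51,010 km, which is inconsistent with its own per-row minimum
(1860 km); the package keeps the per-row values and leaves the discrepancy
alone.

## Migration phenology

The phenology follows the absolute-displacement method with a spatial
gate. Per UTC+9 date, `daily_series()` sums consecutive-fix step distances
(each step assigned to the date of its **start** fix, so a leg beginning
at 23:00 counts entirely toward that date) and takes the spherical mean of
the day's fixes. A date with a single fix has distance 0 and can never be
active. A day is **active migration** when distance > 60 km (strict, "more
than") *and* the daily mean latitude lies in 40.9–64.9°N inclusive. The
latitude gate uses the daily spherical mean — the method needs one
representative daily position and the mean is the obvious summary; this
was a genuinely open choice.

Migratory windows span first to last active day per season. Active days
are split into seasons at the summer band: before 7 Jun → spring of that
year, after 31 Aug → autumn; the handful of within-band summer active days
(local movement at high latitude) belong to neither. This summer-band
split, rather than a mid-year split, matches the empirically empty
latitude band between migrations. Population windows pool all birds;
per-bird activity within them is reported both against the window duration
and against the days the bird actually has data inside the window (the
correction for monitoring gaps — another open point, resolved by reporting
both).

Season bands: winter 18 Dec–12 Apr (wrapping the year; 18–31 Dec belongs
to the following winter's label), spring 13 Apr–6 Jun, summer 7 Jun–31
Aug, autumn 1 Sep–17 Dec.

## Solar geometry and bouts

Solar elevation uses a self-contained implementation of the NOAA solar
calculator (Meeus low-accuracy solar position plus the standard
atmospheric refraction polynomial), accurate well under 0.1° in
1900–2100 — far finer than the classification needs. The diel threshold is
**−6°**, the civil-twilight limit. The source convention "below 6 degrees"
would, read literally as +6°, misname civil twilight (the sun 0–6° *below*
the horizon); the threshold is therefore signed, default −6, and
configurable. A bout is *night* when both endpoints — each evaluated at
its own position and instant, since the bird moves — are below the
threshold, *day* when both are at or above it, *twilight* when mixed. The
both-endpoints rule is forced by the twilight definition.

Bouts are consecutive fix pairs with durations in 1.9–2.1 h (the tolerance
around a 2 h duty cycle; other pairs are dropped). Migration bouts move
strictly more than 5 km. Bout altitude is the endpoint mean after flooring
negatives at zero (small negative GPS altitudes over water are measurement
noise); a missing endpoint altitude makes the bout's altitude missing, and
such bouts still contribute to rate and diel analyses. Bout month comes
from the start fix in UTC+9. Monthly diel compositions pool bouts across
birds by default, with per-bird equal weighting as an option — whether the
original figures pooled or weighted is unknowable from their captions, and
pooling is the simpler default.

Rank tests delegate their p-values to `stats::wilcox.test`: the
Mann–Whitney test is exact when both groups have ≤ 8 untied observations,
the signed-rank test when there are < 50 untied nonzero differences
(zero differences are dropped first, Wilcoxon's original treatment);
otherwise the normal approximation with tie and continuity corrections is
used. The package adds the signed continuity-corrected Z deviate, the form
in which such tests are usually quoted.

## Route repeatability (DTW)

Tracks are regularized to daily positions by linear interpolation in time
along the great-circle segment between bracketing fixes (spherical linear
interpolation of unit vectors), never extrapolating beyond the observed
range; interpolation across gaps longer than 7 days is flagged rather than
suppressed, since the original handling of long gaps is unknown. Daily
positions are projected with a spherical Lambert azimuthal equal-area
projection centered on the cohort's spherical mean position (the center is
configurable; none is published).

Dynamic time warping is the classic dynamic program over boundary-matched
monotone alignments with steps (i−1,j), (i,j−1), (i−1,j−1) and no warping
window, so segments of different lengths and speeds are comparable. The
pointwise metric is Euclidean distance in the common projected plane, in
km — scale-meaningful and antimeridian-safe; a great-circle point metric
on raw coordinates is available as an option. The reported value is the
raw cumulative distance, matching the convention of the R implementation
tradition this analysis comes from; path-length normalization is offered
because raw values grow with segment length.

Within-individual DTW values (same bird, different years) are compared to
between-individual values by randomization: group labels are reshuffled
`n_perm` times (default 10,000) and the two-sided p-value is
`(1 + #{|null| ≥ |observed|}) / (n_perm + 1)` — the add-one estimator, so
p is never exactly zero. Fixed seeds make permutation results exactly
reproducible.

Between-year timing consistency is reported as absolute day-of-year
differences at the four window endpoints; no formal repeatability
coefficient is computed (deliberately out of scope — the sample sizes this
design targets cannot support one).

## Connectivity and utilization distributions

Migratory connectivity is the Mantel correlation between the pairwise
great-circle distance matrix of per-bird breeding centroids (spherical
mean of summer-band fixes) and that of wintering centroids (winter-band
fixes): the Pearson correlation of the strictly lower triangles. How the
original analysis formed per-bird points is unstated; season-band
centroids are the natural choice. The 95 % CI resamples birds with
replacement (default 1000 draws, percentile method), rejecting degenerate
resamples with fewer than three distinct birds or a zero-variance
triangle.

Utilization distributions are isotropic Gaussian kernel densities on a
regular grid in the projected plane. The "smoothing factor of 100 km" is
interpreted as the kernel standard deviation (the home-range convention
for a smoothing parameter; the original kernel form is unstated, and
Gaussian is the default choice). The grid pads three bandwidths beyond the
data and the density is normalized to integrate to 1; isopleths take cells
in decreasing density order until the requested mass is covered. To weight
birds equally, restrict input positions to each bird's first tracked year
upstream (as `run_pipeline()` does).

## The synthetic generator

`generate_cohort()` scripts each bird-year as: winter residence → spring
migration along a bird-specific coastal corridor → summer residence →
autumn migration → winter residence, emitting fixes at the duty cycle and
injecting failed 0/0 fixes and timestamp duplicates at configured rates.
Its defaults are the study conditions the analyses assume:

- wintering sites 35–43°N / 127–141°E; breeding sites 65.2–69°N /
  155–175°E, linked by a fixed coastal corridor (East Sea coast, Sakhalin,
  Sea of Okhotsk, Kolyma uplands);
- spring departures ~24 April (SD 5 d), autumn departures ~25 August
  (SD 12 d, the wider autumn spread);
- travel days average 300 km/day (SD 50, floored at 100);
- stopovers: spring mean 1.5 × ~2 d, autumn mean 5 × ~5 d — autumn
  migration windows are therefore longer with a lower active-day share,
  while daily travel rates are season-symmetric;
- 12 % of travel days move in a pre-dawn night window (00–06 KST), the
  rest in a day window (07–19 KST); moving fixes carry higher altitudes
  (mean 400 m, rare 1000–3500 m excursions), resident fixes low altitudes
  that can dip below zero, exercising the altitude floor;
- per-fix route jitter 5 km SD on moving fixes; residence/stopover wander
  1.0 km SD; per-bird corridor offsets 30 km SD (the bird-specific routes
  that make within-individual DTW smaller than between);
- failure rate 1 %, duplicate rate 0.5 %.

The residence wander scale deserves a note: with 2 h fixes, i.i.d. jitter
of σ km puts a Rayleigh tail of consecutive displacements above the 5 km
migration-bout threshold. At σ = 1.5 km about 6 % of stationary bouts
cross it — an artifact of the i.i.d. wander model, not an emulated
behaviour — so the default is σ = 1.0 km, where the artifact is rare and
non-travel daily path sums (~14 km) stay far below the 60 km activity
threshold.

Ground truth (scripted daily distances and mean latitudes from the
noise-free positions, derived window endpoints under the 60 km / latitude-
band definition, injected artifact counts) is returned alongside the
fixes, so recovery is checkable exactly: with zero noise the pipeline
reproduces scripted windows to the day and daily distances to floating-
point precision; with 10 km jitter, window endpoints stay within ±1 day.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: coastline-following detail and weather-driven
detours, wind support and airspeeds, behaviourally structured foraging
(wander is i.i.d. jitter, not commuting trips), GPS altitude error
structure, solar-panel-driven duty-cycle irregularity, tag failure
processes correlated with behaviour, and partial-year deployments starting
mid-cycle.

## Numerical choices and degenerate inputs

- Sphere radius 6371.0088 km everywhere; printed distances are at km
  precision and insensitive to the choice.
- Spherical interpolation uses slerp on unit vectors with a small-angle
  fallback; the equal-area projection errors at the center's antipode and
  round-trips to < 1 m within 6000 km.
- `spherical_mean()` errors on a zero resultant (antipodally balanced
  input); fate classification needs ≥ 2 terminal fixes to call
  stationarity; tracks with < 2 fixes have zero path length; a
  single-bird cohort reports an `NA` standard deviation rather than a
  number.
- Strict inequalities follow the "more than" wording: > 60 km days,
  > 5 km bouts. Boundary dates are inclusive as listed for the season
  bands.
- Permutation and bootstrap helpers save and restore the caller's RNG
  state when given a seed, so seeded calls do not disturb surrounding
  randomness.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make every check sharp
but cheap: oracle comparisons use 200–1000 random cases (geometry pairs,
DTW path enumerations up to 6×6); calibration checks use 200 permutation
replicates, 500 Mantel permuted-destination replicates and 1000 rank-test
null replicates; end-to-end recovery uses cohorts of 10 birds × 1 year at
a 2 h duty cycle and 40 replicate 5-bird × 2-year cohorts at 12 h for the
DTW separation rate. The full suite runs in a few minutes on one core.

## Known limitations

- Distances are spherical, not ellipsoidal; at the km precision of the
  outputs this is immaterial, but sub-km geodesy should use a geodesic
  library.
- The phenology is threshold-based; it does not segment tracks
  probabilistically and will miss slow migration below 60 km/day by
  construction (the fly-and-forage share is reported separately for
  exactly this reason).
- Daily regularization linearly interpolates across transmission gaps;
  gap-flagged positions should be treated cautiously in DTW and UD
  outputs.
- The Mantel formulation measures one specific notion of connectivity
  (distance-matrix correlation); transition-probability estimators are
  out of scope.
- Printed reference-cohort quantities are reproduced exactly, but
  data-dependent results of the original field study (window dates, test
  statistics, connectivity estimates) require the unavailable raw tracks
  and are deliberately not targets.
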