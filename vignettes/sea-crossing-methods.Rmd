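---
title: "Methods: reconstructing and modelling nocturnal sea-crossing flights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing and modelling nocturnal sea-crossing flights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightcross)
```

This vignette explains what `nightcross` computes and why it computes it
that way: the track-geometry model and its conventions, the solar and
atmospheric sub-models, the wind-triangle calculation, the statistical
layer, and — because the package ships its own synthetic study system —
exactly what that generator does and does not emulate.

## The measurement setting

The pipeline is designed around a sparse but structured tagging protocol
for a nocturnal migrant crossing water barriers:

* GPS tags record **two fixes per night**, at 21:00 and 23:00 UTC. Over a
  crossing night these are the only positions available, so everything
  else — where the bird entered the water, when it will reach the far
  shore — must be reconstructed under a uniform-motion assumption.
* Multisensor loggers sample **ambient pressure** (hourly, or every 5 min
  in later tag generations) and **vertical acceleration** in bursts of 5 or
  10 samples at 100 ms, aggregated to intervals of 60 or 120 burst flags.
* **Gridded winds** (reanalysis-style) are available at the surface and at
  the 1000, 925, 850 and 700 hPa levels, corresponding to roughly 10, 100,
  750, 1500 and 3000 m above sea level.
* **Trapping records** give body mass and local trapping hour for birds
  intercepted on the morning after a crossing.

## Track geometry

Tracks are great-circle polylines through the fixes on a sphere of radius
6371.0088 km (the IUGG mean radius). At the accuracy relevant here —
shoreline transitions refined to ~0.1 m, nightly fixes hundreds of
kilometres apart — an ellipsoidal model would change distances by well
under the tolerances used anywhere in the package, so the sphere is kept
for its exact closed forms.

**Shoreline intersection.** Land polygons (lon/lat, WGS84) are intersected
with the track by densifying each leg at a configurable step (default
1 km), classifying each vertex with an even-odd point-in-polygon test, and
refining every land/water transition by bisection along the geodesic until
the bracketing points are less than 0.1 m apart. Legs that cross the
antimeridian are split at ±180° first so longitudes never wrap within a
piece. The result is an ordered list of shoreline transitions and the
land/water spans between them; spans touching a track end are flagged
unbounded (a track entirely over water is one unbounded water span — a
signal, not an error).

**Open-water distance (OWD).** Defined as the length of the longest
contiguous water span. This makes archipelago cases deterministic: a
150/5/60 km gap sequence has OWD 150, not 215. Summing all spans is
available as an explicit option (`owd_method = "sum"`) for users who want
total water exposure instead of the maximum unbroken barrier.

**Ground speed and crossing times.** The crossing ground speed is the
great-circle separation of the two nightly fixes divided by the 2-h
sampling interval. Crossing initiation and arrival are extrapolated from
the fixes at that speed. Both along-track distances are **signed**: if the
bird already passed the arrival shoreline before the 23:00 fix, the
remaining distance is negative and the formula still returns the correct
arrival time under uniform motion. A `bracketed` flag records whether both
fixes fell strictly inside the water span; the uniform-speed reconstruction
is exact on synthetic data whenever motion is uniform, bracketed or not,
but on real data the estimate degrades the further the fixes sit from the
crossing.

**What is not modelled.** Route choice and detour optimisation are out of
scope; tracks with missing nightly fixes around the crossing are dropped
with a warning rather than imputed.

## Day/night classification

Sunrise and sunset come from the standard NOAA solar-position algorithm
(low-accuracy Meeus ephemeris, fixed-point iteration on the event time),
which is accurate to well under 2 min below the polar circles. Daylight is
delimited by the conventional refraction-corrected zenith of 90.833°; civil
twilight is deliberately **not** used, and the boundary instants count as
daylight so the classification is deterministic. Polar day/night return a
flag instead of fabricated times. An arrival is diurnal when it falls
between sunrise and sunset at the arrival shoreline on the arrival's UTC
calendar day.

## Logger processing

**Altitude.** Pressure converts to altitude by the International Standard
Atmosphere closed form with T0 = 288.15 K, L = −0.0065 K m⁻¹,
P0 = 1013.25 hPa, g = 9.81 m s⁻², R0 = 287.053 J kg⁻¹ K⁻¹. Altitudes are
standard-atmosphere values, not corrected for local weather — consistent
with how such data are reported. Near sea level the sensitivity is about
8 m per hPa, so with ~±1 hPa sensor accuracy, "below 10 m" statements
carry that uncertainty.

**Activity.** The activity index of an interval is simply
`n_active / n_samples`. The per-burst activity criterion used to produce
`n_active` on real loggers is proprietary to the tag firmware; the
package's `burst_is_active()` uses peak-to-peak amplitude over a
configurable threshold (default 2 m s⁻²), which reproduces the obvious
limiting behaviours (constant signal inactive, large-amplitude flapping
active, detections monotone in the threshold).

**Episode segmentation.** A flight episode is a maximal run of intervals
whose centred 3-interval rolling mean activity stays ≥ 0.5 for at least
30 min, with single-interval dropouts bridged. These defaults recover
planned synthetic episodes to within one interval; on real data they are
tuning knobs, exposed as arguments.

**Periods.** UTC hour labels 21–23 and 0–3 are night, 6–16 are day, the
rest unassigned. Night intervals before an episode's first day block are
N1, after it N2. The hour windows are inclusive label sets, so 22:00 → N1,
10:00 → D, 17:00 → unassigned, and every sample receives exactly one label.

**Sea-crossing identification.** Episodes are flagged as sea crossings by
either of two independent criteria: (i) positions interpolated between
known anchor locations at an assumed fixed ground speed (default 10 m s⁻¹)
place part of the episode over water; (ii) the episode contains ≥ 2 h of
daylight flight below 10 m altitude — prolonged surface skimming is only
possible over open water, which makes it a useful validation signal when
anchors are missing. The 10 m / 2 h thresholds are conventions, set well
above the pressure-noise floor and well below a plausible overland
low-flight duration, and are exposed in the API.

**Vertical speed** is computed by central finite differences (one-sided at
the ends), which is unbiased for smooth trajectories at these sampling
rates.

## Wind support and the two altitude-use hypotheses

At each whole hour the track position is interpolated, the local
great-circle bearing taken as the preferred direction, and the wind sampled
by multilinear interpolation in longitude, latitude and time at each level.
With along-track wind $w_\parallel$ and cross-track wind $w_\perp$, a bird
holding airspeed $a$ (default 10 m s⁻¹) and offsetting its heading to
cancel drift achieves ground speed

$$ v_g = w_\parallel + \sqrt{a^2 - w_\perp^2}, $$

infeasible when $|w_\perp| > a$. Infeasible hours are excluded from
summaries and counted, rather than silently assigned a drifting ground
speed — whether drift should be credited is a modelling question the user
can answer downstream. Track-level summaries use the **harmonic** mean of
hourly ground speeds, the correct travel-time average over a fixed
distance. Hypothesis H1 takes the per-hour maximum across levels before
averaging; H2 uses one fixed nocturnal level, chosen as the analysis level
nearest the mean GPS altitude after excluding negative altitudes and values
locked to 250-m intervals (a known artefact of the GPS altitude solver).
By construction H1's harmonic mean dominates H2's, which the test suite
asserts on arbitrary fields.

## Statistical layer

* **Diurnal-arrival model:** binomial mixed logistic regression,
  `diurnal ~ owd + v_g + completed + (1 | individual)`, fitted by maximum
  likelihood with `glmmTMB`. A constant response is reported as a
  complete-separation flag, not a fit. When the random-intercept variance
  is estimated at the boundary (effectively zero) the joint Hessian is
  singular; the fixed effects remain valid and the condition is reported
  as a flag rather than a failure.
* **Period and wind-assistance models:** linear mixed models
  (`lmerTest::lmer`) with individual or track random intercepts, pairwise
  contrasts on estimated marginal means with the Tukey studentized-range
  adjustment (`emmeans`).
* **One-sample t test** from summary statistics, two-sided.
* **Body-mass regression:** OLS of mass on local trapping hour; exact on
  noiseless data, adjusted R² reported.
* **Fuel fraction:** `(mass − lean) / lean` with lean mass 71.3 g by
  default.

Two-sided p-values and α = 0.05 throughout; the Tukey adjustment is the
only multiplicity correction applied.

## The synthetic study system

The generator reproduces the *sampling design*, not the full ecology:

* **Coastlines** are analytic latitude bands around a reference meridian —
  a strait, two gaps with an island, or an archipelago — so the true OWD
  and shoreline latitudes are known in closed form. Real shorelines are
  fractal; none of the geometry tests say anything about coastline-data
  resolution effects.
* **Tracks** fly due north at constant ground speed, departing in the
  evening south of the first shoreline. Fixes appear exactly at the
  configured UTC hours. Truth records carry the exact initiation time, OWD
  and arrival time; the round-trip tests require recovery within 1 km and
  5 min and an exact day/night label. Real birds accelerate, drift and
  meander; the uniform-speed assumption is the same one the downstream
  estimator makes, so these tests validate the geometry, not the
  biological assumption.
* **Sensor streams** place pressure at the inverse-ISA value for the
  planned altitude plus Gaussian noise (SD 1 hPa, the stated sensor
  accuracy) and draw per-interval active counts as
  Binomial(n_samples, mode mean) with mode means 0.975 (nocturnal
  flapping), 0.828 (diurnal flap-glide) and 0 (roost). The binomial choice
  is the simplest model matching the stated moments; real activity counts
  are likely overdispersed.
* **Trapping records** follow mass = 83.9 − 1.29·hour + N(0, 5.06) g with
  hours uniform on the 04–11 h protocol window. The noise SD is not a
  published quantity; 5.06 g is derived so that the regression's adjusted
  R² is ≈ 0.21 given the slope and the hour spread, i.e. the generator is
  calibrated to the reported fit quality rather than to an assumed
  measurement error.
* **Crossing tables for model recovery** (83 flights, 24 individuals) draw
  ground speed from the field marginal N(16.35, 5.19²) m s⁻¹ and barrier
  distance positively associated with it
  (`owd = 30 + 15·v_g + N(0, 40)` km, floored at 30). The association
  matters: with the regression coefficients used as truth, *independent*
  covariates of realistic spread push most fitted probabilities to 0 or 1,
  and the binomial-GLMM likelihood then genuinely prefers a degenerate
  large-variance random intercept (quasi-separation) — Wald intervals
  break down for any fitter. The precision of the reference fit implies
  the field covariates were jointly moderate, which the positive
  association reproduces (longest crossings attempted under the strongest
  wind support); under it, simulated-study Wald coverage is nominal and
  about 40% of arrivals are diurnal. This is the one place where the
  generator encodes an inferred, not printed, feature of the study data.
* **Period tables** draw per-episode activity from Beta distributions with
  the printed per-period means and SDs (0.975 ± 0.0271, 0.828 ± 0.0476,
  0.939 ± 0.0383) at n = (85, 30, 19) over 18 individuals. Beta residuals
  keep fractions in [0, 1] *with the stated moments exactly*; truncated
  Gaussians would bias the first-night mean noticeably (the 97.5% mean
  sits less than one SD below 1). Because the generating SDs differ by
  period while the fitted model — like the reference analysis — assumes a
  common residual variance, per-period model-based intervals are not
  exactly calibrated; recovery is therefore asserted on the N1−D contrast
  and on estimator bias (< 0.25 sampling SD), not on per-mean coverage.

All generators restore the caller's RNG state and are bit-identical under
the same seed.

## Problem sizes and numerical choices

The recovery suites use 200 replicates for the crossing GLMM and body-mass
OLS and 100 for the period LMM, at the field sample sizes (83/24, 95,
85/30/19) — enough that a 95% coverage estimate has ~1.5% Monte-Carlo
error while the whole suite stays comfortably interactive. Shoreline
bisection stops at 0.1 m; wind interpolation is exact at grid nodes;
harmonic means exclude non-positive speeds with an explicit count;
equality at period-hour boundaries and solar events is resolved by the
inclusive conventions stated above.

## Known limitations

* The uniform-speed reconstruction inherits all the caveats of two fixes
  per night: speed is a single 2-h sample, and multi-night crossings with
  missing fixes are flagged, not segmented.
* Solar times assume the arrival's UTC calendar day is the local solar
  day, which holds for the longitudes this workflow targets (roughly
  Europe/Africa) but would need a longitude-aware day shift near the
  dateline.
* The wind module evaluates fixed hypotheses (H1/H2); it does not optimise
  altitude trajectories or model ground effect, wave soaring, or thermal
  assistance.
* The synthetic system validates the pipeline's internal consistency.
  Passing its tests demonstrates correct geometry, timing, and estimator
  behaviour under the stated assumptions — not that those assumptions hold
  for any particular real data set.
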