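# nightcross

Analysis toolkit for open-water crossings by nocturnally migrating
land-birds, built around the kind of biologging data collected on European
nightjars (*Caprimulgus europaeus*): nightly GPS fixes, multisensor loggers
recording ambient pressure and vertical acceleration, gridded wind fields,
and morning trapping records. It is aimed at movement ecologists who want to
go from raw tag tables to crossing-level quantities and the statistical
models usually fitted on them, and at methods developers who need a fully
synthetic, ground-truthed test bed for such pipelines.

## What it computes

**Track geometry.** Tracks are great-circle polylines through the nightly
fixes (sphere radius 6371.0088 km). Intersecting a track with coastline
polygons yields the shoreline crossing points p_A and p_B; the open-water
distance (OWD) is the along-track length of the longest contiguous water
span. Ground speed is estimated from the two nightly fixes p_1, p_2 taken
2 h apart:

    V_g = d(p_1, p_2) / Δt

and crossing times are reconstructed by extrapolating at V_g:

    t_init = t(p_1) − d(p_A, p_1) / V_g,    t_arr = t(p_2) + d(p_2, p_B) / V_g.

**Day/night classification.** Sunrise and sunset from standard NOAA solar
geometry (refraction zenith 90.833°); an arrival is diurnal when it falls
between sunrise and sunset at p_B (boundaries count as daylight).

**Logger processing.** Pressure converts to altitude by the International
Standard Atmosphere closed form

    z = (T0 / L) ((P0 / P)^(L·R0/g) − 1)

with T0 = 288.15 K, L = −0.0065 K m⁻¹, P0 = 1013.25 hPa, g = 9.81 m s⁻²,
R0 = 287.053 J kg⁻¹ K⁻¹ (about 8 m per hPa near sea level). The
flight-activity index of an accelerometer interval is the active fraction
of its 60 or 120 burst samples; episodes are maximal high-activity runs,
summarized over the first-night / day / second-night (N1/D/N2) UTC-hour
periods.

**Wind support.** Winds sampled along hourly interpolated track positions
at the surface and the 1000/925/850/700 hPa levels; achievable ground speed
at fixed airspeed (default 10 m s⁻¹) with the heading offset that cancels
crosswind, `w∥ + sqrt(airspeed² − w⊥²)`; harmonic-mean ground speeds under
hypothesis H1 (best level each hour) and H2 (fixed nocturnal level).

**Statistics.** Binomial mixed logistic regression of diurnal arrival on
barrier distance, ground speed and completed distance (individual random
intercept); period-contrast and wind-assistance linear mixed models with
Tukey-adjusted contrasts; one-sample t test from summary statistics; the
morning body-mass regression and fuel fraction relative to lean mass.

**Synthetic data.** `sim_config()` and the `generate_*()` functions build
coastlines with exact analytic geometry, crossing tracks with known truth
records, sensor streams, wind grids and trapping tables, so every stage
above can be validated against ground truth.

## Worked example

```r
library(nightcross)

coast <- generate_coastline("strait", widths_km = 200)   # 200-km water gap
cfg   <- sim_config(seed = 7)
tr    <- generate_track(cfg, "bird01", true_groundspeed = 16.35, coast)
cr    <- extract_crossings(tr$fixes, coast)
cr[, c("owd_km", "v_g_ms", "completed_km", "t_init", "t_arr", "diurnal")]
#>   owd_km v_g_ms completed_km              t_init               t_arr diurnal
#> 1    200  16.35        87.72 2020-09-05 19:30:34 2020-09-05 22:54:27   FALSE
```

The recovered open-water distance equals the constructed strait width, the
ground speed from the 21:00/23:00 fix pair matches the true speed, and the
bird is (correctly) classified as arriving at night: 200 km at 16.35 m s⁻¹
takes 3.4 h, finishing well before sunrise.

```r
r <- one_sample_t(16.35, 5.19, 83, 10)   # are crossing speeds above airspeed?
#> t = 11.15, df = 82, p = 4.2e-18

fit_diurnal_glmm(simulate_crossing_table(seed = 1))
#> Model: diurnal_glmm
#> n = 83 observations, 24 groups; converged: TRUE
#>          term  estimate      se statistic         p
#>   (Intercept)  1.579227 1.42153    1.1109 0.2665952
#>        owd_km  0.051839 0.01622    3.1964 0.0013914
#>        v_g_ms -1.031602 0.30238   -3.4117 0.0006457
#>  completed_km -0.004715 0.01304   -0.3616 0.7176630
```

The simulated study (83 crossings, 24 individuals) is generated from known
coefficients; the refit recovers a positive barrier-distance effect and a
negative ground-speed effect on the probability of a daylight arrival —
wider barriers push flights into the day, faster birds finish in the dark.

A command-line front end for the same steps lives at
`inst/scripts/nightcross.R` (`simulate`, `crossings`, `mdl`, `wind`,
`stats`, `run`).

## Documentation

The methods vignette (`vignettes/sea-crossing-methods.Rmd`) describes the
models, the synthetic study system and its calibration, numerical choices,
and known limitations.
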