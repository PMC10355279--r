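test_that("one-sample t matches the closed form and textbook cases", {
  r <- one_sample_t(16.35, 5.19, 83, 10)
  expect_equal(r$t, 11.15, tolerance = 0.005)
  expect_identical(r$df, 82)
  expect_lt(r$p, 0.001)
  expect_equal(one_sample_t(10, 2, 30, 10)$t, 0)
  expect_equal(one_sample_t(10, 2, 30, 10)$p, 1)
  # doubling sd halves t; closed-form agreement on random inputs
  set.seed(8)
  for (i in 1:25) {
    m <- runif(1, -5, 25); s <- runif(1, 0.5, 9); n <- sample(3:200, 1)
    mu <- runif(1, -5, 25)
    r1 <- one_sample_t(m, s, n, mu)
    expect_equal(r1$t, (m - mu) / (s / sqrt(n)), tolerance = 1e-10)
    expect_equal(one_sample_t(m, 2 * s, n, mu)$t, r1$t / 2, tolerance = 1e-10)
    expect_equal(r1$p, 2 * pt(-abs(r1$t), n - 1), tolerance = 1e-12)
  }
})

test_that("fuel fraction is monotone and matches the worked value", {
  expect_equal(fuel_fraction(79.86), 0.120, tolerance = 5e-4)
  expect_equal(fuel_fraction(71.3), 0)
  masses <- seq(65, 95, by = 2.5)
  expect_true(all(diff(fuel_fraction(masses)) > 0))
  expect_error(fuel_fraction(-2), "positive")
})

test_that("body-mass OLS is exact on noiseless data", {
  h <- seq(4, 11, length.out = 20)
  d <- data.frame(hour_local = h, mass_g = 83.9 - 1.29 * h)
  r <- fit_bodymass_ols(d)
  expect_equal(r$coefficients$estimate, c(83.9, -1.29), tolerance = 1e-10)
  expect_equal(r$r2$adjusted, 1, tolerance = 1e-10)
  expect_error(fit_bodymass_ols(d[1:2, ]), "3 records")
  expect_error(fit_bodymass_ols(data.frame(hour_local = rep(6, 5),
                                           mass_g = rnorm(5))), "variance")
})

test_that("zero-slope truth gives near-zero adjusted R squared", {
  cfg <- sim_config(seed = 99, bodymass_slope_g_per_h = 0)
  fits <- vapply(1:40, function(s) {
    d <- generate_trapping_records(cfg, n = 95, seed = s)
    fit_bodymass_ols(d)$r2$adjusted
  }, numeric(1))
  expect_lt(abs(mean(fits)), 0.05)
})

test_that("diurnal GLMM flags degenerate inputs instead of fitting silently", {
  d <- simulate_crossing_table(seed = 4)
  d$diurnal <- FALSE
  r <- fit_diurnal_glmm(d)
  expect_false(r$converged)
  expect_match(r$flags, "separation")
  d2 <- simulate_crossing_table(seed = 4)
  d2$individual <- "only_one"
  expect_error(fit_diurnal_glmm(d2), "two individuals")
})

test_that("diurnal GLMM recovers strong effects on one simulated study", {
  d <- simulate_crossing_table(seed = 2024)
  r <- fit_diurnal_glmm(d)
  ct <- r$coefficients
  expect_identical(ct$term,
                   c("(Intercept)", "owd_km", "v_g_ms", "completed_km"))
  expect_gt(ct$estimate[ct$term == "owd_km"], 0)
  expect_lt(ct$estimate[ct$term == "v_g_ms"], 0)
  expect_true(all(ct$se > 0))
  expect_equal(r$n_obs, 83)
  expect_lte(r$n_groups, 24)
  expect_lt(r$ranef$sd, 1)  # near-boundary individual variance
})

test_that("period LMM estimates means and Tukey contrasts; degenerate input flagged", {
  d <- simulate_period_table(seed = 6)
  r <- fit_period_lmm(d)
  em <- r$emmeans
  expect_equal(em$emmean[em$period == "N1"], 0.975, tolerance = 0.02)
  expect_equal(em$emmean[em$period == "D"], 0.828, tolerance = 0.03)
  n1d <- r$contrasts[r$contrasts$contrast == "N1 - D", ]
  expect_lt(n1d$p, 0.01)
  expect_gt(n1d$estimate, 0)
  single <- transform(d, individual = "b01")
  flagged <- fit_period_lmm(single)
  expect_false(flagged$converged)
  expect_match(flagged$flags, "single individual")
})

test_that("identical period means give no significant contrasts at nominal rate", {
  hits <- vapply(1:30, function(s) {
    d <- simulate_period_table(means = c(0.9, 0.9, 0.9),
                               sds = c(0.03, 0.03, 0.03), seed = s)
    any(fit_period_lmm(d)$contrasts$p < 0.05)
  }, logical(1))
  expect_lt(mean(hits), 0.25)
})

test_that("wind contrast model detects a jet and excludes incomplete tracks", {
  make_summaries <- function(h1_boost, seed) {
    set.seed(seed)
    tracks <- sprintf("trk%02d", 1:12)
    do.call(rbind, lapply(tracks, function(id) {
      base <- rnorm(1, 10, 0.5)
      data.frame(track = id,
                 condition = c("surface", "H1", "H2"),
                 groundspeed = base + c(0, h1_boost, 0) + rnorm(3, 0, 0.4))
    }))
  }
  r <- fit_wind_contrast_lmm(make_summaries(6, 1))
  sh1 <- r$contrasts[r$contrasts$contrast == "surface - H1", ]
  expect_lt(sh1$p, 0.01)
  expect_lt(sh1$estimate, 0)  # surface slower than best level
  # null: no significant contrasts most of the time
  hits <- vapply(1:20, function(s)
    any(fit_wind_contrast_lmm(make_summaries(0, s))$contrasts$p < 0.05),
    logical(1))
  expect_lt(mean(hits), 0.3)
  # incomplete track dropped with a warning
  d <- make_summaries(6, 2)
  d <- d[!(d$track == "trk01" & d$condition == "H2"), ]
  expect_warning(r2 <- fit_wind_contrast_lmm(d), "trk01")
  expect_equal(r2$n_groups, 11)
})
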