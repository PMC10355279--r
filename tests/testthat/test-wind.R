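wind_times <- utc("2020-09-05 12:00:00") + (0:6) * 6 * 3600

test_that("wind sampling interpolates multilinearly and hits grid nodes exactly", {
  f <- generate_wind_field(list(`850` = list(u = 5, v = 0, sd = 0),
                                default = list(u = 0, v = 0, sd = 0)),
                           bbox = c(10, 20, 52, 60), times = wind_times)
  w <- sample_wind(f, wind_times[2] + 3 * 3600, c(13.7, 55.9), "850")
  expect_equal(w$u, 5); expect_equal(w$v, 0)
  expect_equal(sample_wind(f, wind_times[1], c(12.5, 54.5), "surface")$u, 0)
  # node value exact on a noisy field
  fn <- generate_wind_field(list(default = list(u = 2, v = -1, sd = 1.5)),
                            bbox = c(10, 20, 52, 60), times = wind_times,
                            seed = 99)
  node <- fn[fn$level == "surface" & fn$lat == 54.5 & fn$lon == 15 &
               fn$time == wind_times[3], ]
  w2 <- sample_wind(fn, wind_times[3], c(15, 54.5), "surface")
  expect_equal(w2$u, node$u); expect_equal(w2$v, node$v)
  expect_error(sample_wind(f, wind_times[1], c(40, 55), "surface"), "outside")
})

test_that("midpoint interpolation between nodes is linear", {
  t2 <- wind_times[1:2]
  f <- generate_wind_field(list(default = list(u = 0, v = 0, sd = 0)),
                           bbox = c(10, 15, 54, 56.5), times = t2,
                           grid_step_deg = 2.5)
  # two-node contrast along latitude: v = 0 at lat 54, v = 2 at lat 56.5
  f$v[f$lat == 56.5] <- 2
  w <- sample_wind(f, t2[1], c(12.5, 55.25), "surface")
  expect_equal(w$v, 1)
})

test_that("heading compensation solves the wind triangle", {
  r0 <- ground_speed_with_heading_compensation(0, 0, 0, 10)
  expect_equal(r0$groundspeed, 10); expect_equal(r0$wind_profit, 0)
  # pure tailwind on a northward track
  rt <- ground_speed_with_heading_compensation(0, 6, 0, 10)
  expect_equal(rt$groundspeed, 16); expect_equal(rt$heading_deg, 0)
  # pure crosswind: ground speed sqrt(100 - 36), heading into the wind
  rc <- ground_speed_with_heading_compensation(6, 0, 0, 10)
  expect_equal(rc$groundspeed, 8)
  expect_equal(rc$wind_profit, -2)
  expect_equal(rc$heading_deg, (-asin(0.6) * 180 / pi) %% 360, tolerance = 1e-9)
  # crosswind beyond airspeed: infeasible
  ri <- ground_speed_with_heading_compensation(12, 0, 0, 10)
  expect_false(ri$feasible); expect_true(is.na(ri$groundspeed))
  # resultant of airspeed vector + wind is along track (independent check)
  set.seed(7)
  for (i in 1:20) {
    u <- runif(1, -8, 8); v <- runif(1, -8, 8); trk <- runif(1, 0, 360)
    r <- ground_speed_with_heading_compensation(u, v, trk, 10)
    if (!r$feasible) next
    hx <- 10 * sin(r$heading_deg * pi / 180) + u
    hy <- 10 * cos(r$heading_deg * pi / 180) + v
    expect_equal((atan2(hx, hy) * 180 / pi) %% 360, trk %% 360, tolerance = 1e-6)
    expect_equal(sqrt(hx^2 + hy^2), r$groundspeed, tolerance = 1e-9)
  }
})

test_that("feasibility is monotone in airspeed", {
  for (as_ in c(5, 8, 10, 13, 20)) {
    r <- ground_speed_with_heading_compensation(9, 0, 0, as_)
    expect_identical(r$feasible, as_ >= 9)
  }
})

test_that("harmonic mean ground speed behaves like a travel-time average", {
  expect_equal(as.numeric(harmonic_mean_groundspeed(c(10, 10, 10))), 10)
  expect_equal(as.numeric(harmonic_mean_groundspeed(c(10, 20))), 40 / 3,
               tolerance = 1e-9)
  h <- harmonic_mean_groundspeed(c(10, 20, -3, NA))
  expect_equal(attr(h, "n_excluded"), 2)
  set.seed(3)
  for (i in 1:10) {
    v <- runif(5, 1, 30)
    expect_lte(as.numeric(harmonic_mean_groundspeed(v)), mean(v) + 1e-12)
  }
})

test_that("hypothesis evaluation: H1 dominates H2 dominates the worst level", {
  trk <- meridian_track(53.5, 57, "2020-09-05 20:00:00", "2020-09-06 06:00:00")
  # tailwind jet at 850 hPa only
  f <- generate_wind_field(list(`850` = list(u = 0, v = 6, sd = 0),
                                default = list(u = 0, v = 0, sd = 0)),
                           bbox = c(10, 20, 52, 60), times = wind_times)
  prof <- wind_profit_profile(trk, f, airspeed = 10)
  hyp <- evaluate_hypotheses(prof, nocturnal_level = "925")
  s <- hyp$summary
  expect_equal(s$harmonic_mean_groundspeed[s$hypothesis == "H1"], 16)
  expect_equal(s$harmonic_mean_groundspeed[s$hypothesis == "H2"], 10)
  expect_equal(s$harmonic_mean_groundspeed[s$hypothesis == "surface"], 10)
  expect_true(all(hyp$h1_levels$level == "850"))

  # identical winds at all levels: all three agree
  fu <- generate_wind_field(list(default = list(u = 0, v = 3, sd = 0)),
                            bbox = c(10, 20, 52, 60), times = wind_times)
  hyp2 <- evaluate_hypotheses(wind_profit_profile(trk, fu, airspeed = 10), "925")
  expect_equal(length(unique(round(hyp2$summary$harmonic_mean_groundspeed, 9))), 1)

  # H1 matches a brute-force per-hour maximum on a noisy field
  fr <- generate_wind_field(list(default = list(u = 1, v = 2, sd = 2)),
                            bbox = c(10, 20, 52, 60), times = wind_times,
                            seed = 17)
  prof3 <- wind_profit_profile(trk, fr, airspeed = 10)
  hyp3 <- evaluate_hypotheses(prof3, "850")
  brute <- vapply(unique(prof3$time), function(tm) {
    rows <- prof3[prof3$time == tm & prof3$feasible, ]
    max(rows$groundspeed)
  }, numeric(1))
  expect_equal(s3 <- hyp3$summary$harmonic_mean_groundspeed[2],
               length(brute) / sum(1 / brute), tolerance = 1e-9)
  # dominance invariant
  expect_gte(hyp3$summary$harmonic_mean_groundspeed[2],
             hyp3$summary$harmonic_mean_groundspeed[3] - 1e-9)
})

test_that("GPS altitude filtering drops negatives and 250-m locked values", {
  alts <- c(-12, 0, 250, 500, 1337, 820, 1500, 90)
  kept <- filter_gps_altitudes(alts)
  expect_identical(kept, c(1337, 820, 90))
  expect_identical(nearest_level(mean(kept)), "925")
  expect_identical(nearest_level(1400), "850")
  expect_identical(nearest_level(20), "surface")
})
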