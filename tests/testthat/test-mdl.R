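test_that("activity index is the active fraction of burst samples", {
  expect_identical(activity_index(90, 120), 0.75)
  expect_identical(activity_index(45, 60), 0.75)
  expect_identical(activity_index(0, 60), 0)
  expect_warning(activity_index(10, 100), "usual")
  expect_error(activity_index(70, 60), "n_active")
})

test_that("burst activity is peak-to-peak thresholding, monotone in threshold", {
  expect_false(burst_is_active(rep(9.81, 10)))
  expect_true(burst_is_active(9.81 + 5 * sin(seq(0, 2 * pi, length.out = 10))))
  burst <- 9.81 + 1.5 * sin(seq(0, 2 * pi, length.out = 10))
  thresholds <- c(0.5, 1, 2, 4, 8)
  det <- vapply(thresholds, function(th) burst_is_active(burst, th), logical(1))
  expect_true(all(diff(as.integer(det)) <= 0))  # detections only drop as threshold rises
})

test_that("vertical speed uses central differences with one-sided endpoints", {
  t <- seq(0, 1000, by = 100)
  expect_equal(vertical_speed(rep(250, 11), t), rep(0, 11))
  climb <- seq(0, 100, length.out = 11)
  expect_equal(vertical_speed(climb, t), rep(0.1, 11))
  expect_equal(vertical_speed(rev(climb), t), -vertical_speed(climb, t))
})

test_that("flight episodes are segmented from the activity series", {
  cfg <- sim_config(seed = 21)
  night0 <- utc("2020-09-05 20:00:00")
  plan <- data.frame(start = night0, end = night0 + 10 * 3600,
                     mode = "flapping", altitude_m = 1500)
  st <- generate_sensor_stream(cfg, plan)
  ep <- segment_flight_episodes(st)
  expect_equal(nrow(ep), 1)
  # boundaries within one 5-min interval of the plan
  expect_lte(abs(as.numeric(ep$start) - as.numeric(night0)), 300)
  expect_lte(abs(as.numeric(ep$end) - as.numeric(night0 + 10 * 3600)), 600)

  # all-roost stream: nothing detected
  roost <- generate_sensor_stream(cfg, data.frame(
    start = night0, end = night0 + 5 * 3600, mode = "roost", altitude_m = 0))
  expect_equal(nrow(segment_flight_episodes(roost)), 0)

  # two flights separated by a 4-h roost
  plan2 <- data.frame(
    start = c(night0, night0 + 12 * 3600),
    end = c(night0 + 8 * 3600, night0 + 18 * 3600),
    mode = "flapping", altitude_m = 1500)
  st2 <- generate_sensor_stream(cfg, plan2)
  expect_equal(nrow(segment_flight_episodes(st2)), 2)
})

test_that("period assignment follows the UTC hour rule, each sample labelled once", {
  t0 <- utc("2020-09-05 22:00:00")  # N1
  times <- t0 + c(0, 12, 19, 26) * 3600  # 22:00, 10:00, 17:00, 00:00
  per <- assign_periods(times)
  expect_identical(as.character(per), c("N1", "D", "unassigned", "N2"))
  expect_false(any(is.na(per)))
  # without any day block every night sample is N1
  night_only <- assign_periods(t0 + c(0, 1, 2) * 3600)
  expect_identical(as.character(night_only), c("N1", "N1", "N1"))
})

test_that("period summaries recover the planned altitudes and activity contrast", {
  cfg <- sim_config(seed = 33)
  night0 <- utc("2020-09-05 20:00:00")
  plan <- data.frame(start = c(night0, night0 + 10 * 3600),
                     end = c(night0 + 10 * 3600, night0 + 20 * 3600),
                     mode = c("flapping", "flap-glide"),
                     altitude_m = c(cfg$altitude_night_m, cfg$altitude_day_m))
  st <- generate_sensor_stream(cfg, plan)
  ep <- segment_flight_episodes(st)
  ps <- summarize_periods(ep, st)
  expect_setequal(as.character(ps$period), c("N1", "D"))
  n1 <- ps[ps$period == "N1", ]; d <- ps[ps$period == "D", ]
  expect_equal(n1$mean_altitude_m, cfg$altitude_night_m, tolerance = 0.02)
  expect_equal(d$mean_altitude_m, cfg$altitude_day_m, tolerance = 5)
  # nocturnal flapping is more active than diurnal flap-gliding
  expect_gt(n1$mean_activity, d$mean_activity)
  expect_equal(n1$mean_activity, cfg$activity_night_mean, tolerance = 0.02)
  expect_equal(d$mean_activity, cfg$activity_day_mean, tolerance = 0.02)
})

test_that("sea-crossing identification flags by route and by surface skimming", {
  cfg <- sim_config(seed = 5)
  coast <- strait_coast(200)
  night0 <- utc("2020-09-05 20:00:00")
  plan <- data.frame(start = c(night0, night0 + 10 * 3600),
                     end = c(night0 + 10 * 3600, night0 + 20 * 3600),
                     mode = c("flapping", "flap-glide"),
                     altitude_m = c(1500, 5))
  st <- generate_sensor_stream(cfg, plan)
  ep <- segment_flight_episodes(st)
  anchors <- data.frame(t = c(night0 - 3600, night0 + 22 * 3600),
                        lon = 16, lat = c(53.9, 56.5))
  flagged <- identify_sea_crossing(ep, anchors, coast, stream = st)
  expect_true(flagged$route_over_water)
  expect_true(flagged$skimming)
  expect_true(flagged$is_sea_crossing)

  # overland episode at altitude: neither criterion fires
  inland <- data.frame(t = c(night0 - 3600, night0 + 22 * 3600),
                       lon = 16, lat = c(52.2, 52.9))
  st_high <- generate_sensor_stream(cfg, data.frame(
    start = night0, end = night0 + 10 * 3600, mode = "flapping",
    altitude_m = 1500))
  ep_high <- segment_flight_episodes(st_high)
  unflagged <- identify_sea_crossing(ep_high, inland, coast, stream = st_high)
  expect_false(unflagged$route_over_water)
  expect_false(unflagged$skimming)
  expect_false(unflagged$is_sea_crossing)

  # anchors missing: skimming alone still flags
  skim_only <- identify_sea_crossing(ep, NULL, coast, stream = st)
  expect_true(is.na(skim_only$route_over_water))
  expect_true(skim_only$is_sea_crossing)
})
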