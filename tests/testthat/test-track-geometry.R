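test_that("a perpendicular strait crossing yields one water span of the set width", {
  coast <- strait_coast(200)
  trk <- meridian_track(53, 57, "2020-09-05 19:00:00", "2020-09-06 05:00:00")
  inter <- intersect_shoreline(trk, coast)
  water <- inter$spans[inter$spans$water, ]
  expect_equal(nrow(water), 1)
  expect_equal(water$length_km, 200, tolerance = 0.1)
  expect_equal(nrow(inter$transitions), 2)
  expect_identical(inter$transitions$type, c("land_to_water", "water_to_land"))
})

test_that("archipelago crossing yields all gaps, longest first by OWD rule", {
  coast <- generate_coastline("archipelago", c(150, 5, 60))
  trk <- meridian_track(53.5, 57.5, "2020-09-05 19:00:00", "2020-09-06 07:00:00")
  inter <- intersect_shoreline(trk, coast)
  water <- inter$spans[inter$spans$water, ]
  expect_equal(nrow(water), 3)
  expect_equal(sort(water$length_km), c(5, 60, 150), tolerance = 0.1)
  expect_equal(open_water_distance(inter$spans), 150, tolerance = 0.1)
  expect_equal(open_water_distance(inter$spans, "sum"), 215, tolerance = 0.2)
})

test_that("open-water distance handles degenerate span sets", {
  expect_equal(open_water_distance(data.frame(
    start_km = c(0, 150), end_km = c(150, 200),
    length_km = c(150, 50), water = c(TRUE, TRUE))), 150)
  expect_error(open_water_distance(data.frame(
    start_km = 0, end_km = 10, length_km = 10, water = FALSE)), "water")
})

test_that("a track entirely over water is a single unbounded span", {
  coast <- strait_coast(200)
  gaps <- attr(coast, "gaps")
  mid <- (gaps$start_lat + gaps$end_lat) / 2
  trk <- meridian_track(mid - 0.3, mid + 0.3,
                        "2020-09-05 21:00:00", "2020-09-05 23:00:00")
  inter <- intersect_shoreline(trk, coast)
  expect_equal(nrow(inter$spans), 1)
  expect_true(inter$spans$water)
  expect_false(inter$spans$bounded)
})

test_that("open-water distance is invariant to track direction reversal", {
  coast <- generate_coastline("archipelago", c(150, 5, 60))
  trk <- meridian_track(53.5, 57.5, "2020-09-05 19:00:00", "2020-09-06 07:00:00")
  rev_trk <- data.frame(t = trk$t, lon = rev(trk$lon), lat = rev(trk$lat))
  owd_f <- open_water_distance(intersect_shoreline(trk, coast)$spans)
  owd_r <- open_water_distance(intersect_shoreline(rev_trk, coast)$spans)
  expect_equal(owd_f, owd_r, tolerance = 1e-6)
})

test_that("ground speed is distance over elapsed time and scales linearly", {
  p1 <- list(t = utc("2020-09-05 21:00:00"), lon = 16, lat = 56)
  lat_for <- function(km) 56 + km / (6371.0088 * pi / 180)
  p2 <- list(t = utc("2020-09-05 23:00:00"), lon = 16, lat = lat_for(117.72))
  expect_equal(ground_speed(p1, p2), 16.35, tolerance = 1e-4)
  p3 <- list(t = utc("2020-09-05 23:00:00"), lon = 16, lat = lat_for(72))
  expect_equal(ground_speed(p1, p3), 10, tolerance = 1e-6)
  # linear scaling with distance at fixed time difference
  expect_equal(ground_speed(p1, p2) / ground_speed(p1, p3), 117.72 / 72,
               tolerance = 1e-6)
  p_same <- list(t = utc("2020-09-05 23:00:00"), lon = 16, lat = 56)
  expect_equal(ground_speed(p1, p_same), 0)
  expect_error(ground_speed(p2, p1), "later")
})

test_that("crossing times are reconstructed from fix times and ground speed", {
  t1 <- utc("2020-09-05 21:00:00"); t2 <- utc("2020-09-05 23:00:00")
  r <- reconstruct_crossing_times(t1, t2, v_g = 10, completed_km = 72,
                                  remaining_km = 0)
  expect_equal(r$t_init, utc("2020-09-05 19:00:00"))
  r2 <- reconstruct_crossing_times(t1, t2, v_g = 20, completed_km = 0,
                                   remaining_km = 144)
  expect_equal(r2$t_arr, utc("2020-09-06 01:00:00"))
  # fix exactly at the shoreline
  r3 <- reconstruct_crossing_times(t1, t2, v_g = 10, completed_km = 0,
                                   remaining_km = 0)
  expect_equal(r3$t_init, t1)
  expect_error(reconstruct_crossing_times(t1, t2, 0, 10, 10), "positive")
})

test_that("crossing extraction recovers generator truth on a uniform strait crossing", {
  cfg <- sim_config(seed = 11)
  coast <- strait_coast(200)
  # speeds at which the bird is still airborne at both nightly fixes
  for (vg in c(10, 12, 16.35)) {
    tr <- generate_track(cfg, "b1", vg, coast, depart_hour_utc = 19)
    cr <- extract_crossings(tr$fixes, coast)
    expect_equal(nrow(cr), 1)
    expect_lt(abs(cr$owd_km - tr$truth$owd_km), 1)
    expect_lt(abs(as.numeric(cr$t_init) - as.numeric(tr$truth$t_init)), 300)
    expect_lt(abs(as.numeric(cr$t_arr) - as.numeric(tr$truth$t_arr)), 300)
    expect_identical(cr$diurnal, tr$truth$diurnal)
    expect_equal(cr$v_g_ms, vg, tolerance = 1e-3)
  }
})

test_that("an all-land track yields no crossing and a warning", {
  coast <- strait_coast(200)
  trk <- data.frame(individual = "b9",
                    t = utc(c("2020-09-05 21:00:00", "2020-09-05 23:00:00")),
                    lon = 16, lat = c(52.2, 52.8))
  expect_warning(res <- extract_crossings(trk, coast), "no bounded water span")
  expect_equal(nrow(res), 0)
})
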