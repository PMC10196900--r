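test_that("the registry holds 70 uniquely named features with valid sources", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 70)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_setequal(unique(reg$family),
                  c("time", "location", "motion", "communication",
                    "device", "environment"))
  expect_true(all(reg$stream %in% c(names(stream_schemas()), "clock")))
  expect_equal(sum(reg$family == "time"), 2)
})

test_that("accelerometer statistics use the two-stage per-minute scheme", {
  # constant gravity-only signal
  f <- accel_features(t = 0:59, x = rep(0, 60), y = rep(0, 60),
                      z = rep(9.81, 60))
  expect_equal(f$acc_mag_mean, 9.81)
  expect_equal(f$acc_mag_std, 0)
  # two minutes with per-minute means 1 and 3
  f2 <- accel_features(t = c(10, 20, 70, 80), x = c(1, 1, 3, 3),
                       y = 0, z = 0)
  expect_equal(f2$acc_mag_mean, 2)
  expect_equal(f2$acc_mag_max, 3)
  expect_equal(f2$acc_mag_min, 1)
  # random epochs match the loop-based oracle
  set.seed(1)
  for (k in 1:10) {
    n <- sample(5:40, 1)
    t <- sort(runif(n, 0, 900))
    x <- rnorm(n); y <- rnorm(n); z <- rnorm(n, 9.8)
    got <- accel_features(t, x, y, z)
    want <- oracle_accel(t, x, y, z)
    expect_equal(got$acc_mag_mean, want$mean, tolerance = 1e-10)
    expect_equal(got$acc_mag_std, want$std, tolerance = 1e-10)
  }
})

test_that("radius of gyration matches geometric constructions", {
  expect_equal(radius_of_gyration(rep(40.44, 5), rep(-79.99, 5)), 0)
  # two fixes 200 m apart -> 100 m
  dlat <- 200 / (6371000 * pi / 180)
  expect_equal(radius_of_gyration(c(40.44, 40.44 + dlat), c(-79.99, -79.99)),
               100, tolerance = 0.1)
  # n points on a circle of radius R around the centroid -> R
  r_m <- 500
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  rad <- r_m / (6371000 * pi / 180)
  lat <- 40.44 + rad * sin(ang)
  lon <- -79.99 + rad * cos(ang) / cos(40.44 * pi / 180)
  expect_equal(radius_of_gyration(lat, lon), r_m, tolerance = 1)
})

test_that("location entropy matches closed forms", {
  expect_equal(location_entropy(10), 0)
  expect_equal(location_entropy(rep(3, 7)), log(7))
  expect_equal(location_entropy(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_true(is.na(location_entropy(c(0, 0))))
})

test_that("location variance is a translation-invariant population variance", {
  expect_equal(location_variance(rep(40, 4), rep(-80, 4)), 0)
  expect_equal(location_variance(c(0, 0.02), c(0, 0)), 1e-4)
  a <- location_variance(c(40.1, 40.2, 40.15), c(-80, -80.1, -80.05))
  b <- location_variance(c(40.1, 40.2, 40.15) + 3, c(-80, -80.1, -80.05) - 2)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("circadian movement detects a 24-hour rhythm", {
  set.seed(3)
  t <- sort(runif(300, 0, 3 * 86400))
  lat24 <- 40.44 + 0.01 * sin(2 * pi * t / 86400)
  noise <- 40.44 + rnorm(300, 0, sd(0.01 * sin(2 * pi * t / 86400)))
  lon <- rep(-79.99, 300)
  cm_sig <- circadian_movement(t, lat24, lon)
  cm_noise <- circadian_movement(t, noise, lon)
  expect_gt(cm_sig, cm_noise)
  # constant trajectory floors at ln(1e-12)
  expect_equal(circadian_movement(t, rep(40.44, 300), lon), log(1e-12))
  # a 12-hour rhythm leaves little energy in the 23.5-24.5 h band
  lat12 <- 0.01 * sin(2 * pi * t / 43200)
  e24 <- ls_band_energy(t, 0.01 * sin(2 * pi * t / 86400))
  e12 <- ls_band_energy(t, lat12)
  expect_lt(e12, 0.1 * e24)
  # short spans are missing
  expect_true(is.na(circadian_movement(t[t < 43200], lat24[t < 43200],
                                       lon[t < 43200])))
})

test_that("stay points and significant places recover planted anchors", {
  # alternate between two anchors 1 km apart, 30 min at each
  dlat <- 1000 / (6371000 * pi / 180)
  t <- seq(0, 6 * 3600 - 1, by = 300)
  at_b <- (t %/% 1800) %% 2 == 1
  lat <- ifelse(at_b, 40.44 + dlat, 40.44)
  lon <- rep(-79.99, length(t))
  sp <- stay_points(t, lat, lon)
  pl <- significant_places(sp)
  expect_equal(nrow(pl), 2)
  # dwell-weighted: a single anchor yields one place
  pl1 <- significant_places(stay_points(t, rep(40.44, length(t)), lon))
  expect_equal(nrow(pl1), 1)
  # tightening the merge radius never reduces the place count
  counts <- vapply(c(800, 400, 200, 100, 50),
                   function(r) nrow(significant_places(sp, cluster_radius_m = r)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("home designation and travel distance follow the trajectory", {
  # a participant who never leaves home
  t <- seq(0, 2 * 86400 - 1, by = 600)
  lat <- rep(40.44, length(t)); lon <- rep(-79.99, length(t))
  f <- gps_window_features(t, lat, lon,
                           place = rep(1L, length(t)),
                           home_lat = 40.44, home_lon = -79.99)
  expect_equal(f$time_at_home, 1)
  expect_equal(f$travel_distance, 0, tolerance = 1e-6)
  # two fixes 1 km apart travel ~1000 m
  dlat <- 1000 / (6371000 * pi / 180)
  f2 <- gps_window_features(c(0, 600), c(40.44, 40.44 + dlat),
                            c(-79.99, -79.99))
  expect_equal(f2$travel_distance, 1000, tolerance = 1)
  # generator-known homes are recovered by the place pipeline
  co <- tiny_cohort(n_participants = 3, n_weeks = 2, seed = 6)
  ev <- build_events(co$ema, co$participants, seed = 1)
  prep <- prepare_cohort(co$streams, ev)
  truth_home <- co$truth$anchors[anchor == "home"]
  for (pid in truth_home$participant_id) {
    h <- prep$homes[participant_id == pid]
    th <- truth_home[participant_id == pid]
    expect_lt(haversine_m(h$home_lat, h$home_lon, th$lat, th$lon), 150)
  }
})

test_that("communication, device and wifi features follow count semantics", {
  f <- comm_features()
  expect_true(all(unlist(f) == 0))
  f2 <- comm_features(kind = c("call_in", "call_in"), duration = c(60, 90),
                      contact_id = c("a", "a"))
  expect_equal(f2$n_calls_in, 2)
  expect_equal(f2$call_dur_in, 150)
  expect_equal(f2$n_contacts, 1)

  d <- device_features(t = c(0, 300), kind = c("screen_on", "screen_off"),
                       app_id = NA, battery_pct = NA, charging = NA,
                       w_end = 3600)
  expect_equal(d$screen_use_duration, 300)
  expect_equal(d$n_screen_on, 1)
  d2 <- device_features(t = c(0, 10, 20), kind = rep("app_foreground", 3),
                        app_id = c("A", "B", "A"), battery_pct = NA,
                        charging = NA, w_end = 3600)
  expect_equal(d2$n_unique_apps, 2)
  expect_equal(d2$n_app_switches, 2)
  d3 <- device_features(t = c(0, 1800, 3600), kind = rep("battery", 3),
                        app_id = NA, battery_pct = c(40, 70, 100),
                        charging = c(TRUE, TRUE, TRUE), w_end = 3600)
  expect_equal(d3$charging_duration, 3600)
  expect_equal(d3$battery_pct_max, 100)

  expect_equal(wifi_feature(numeric(0)), 0L)
  expect_equal(wifi_feature(ids = list(c("a", "b"), c("b", "c"))), 3L)
  expect_equal(wifi_feature(c(2, 5, 5)), 5L)
})

test_that("instances carry all 70 features with missingness semantics", {
  co <- tiny_cohort(n_participants = 3, n_weeks = 2, seed = 4)
  ev <- build_events(co$ema, co$participants, seed = 1)
  # strip all communication so its counts are true zeros, and all GPS for
  # one participant so location is missing, never zero-filled
  pid <- ev$participant_id[1]
  co$streams$comm <- co$streams$comm[participant_id == "nobody"]
  co$streams$gps <- co$streams$gps[participant_id != pid]
  prep <- prepare_cohort(co$streams, ev)
  inst <- build_instances(prep, 3, 1)
  reg <- feature_registry()
  expect_true(all(reg$name %in% names(inst)))
  expect_equal(sum(names(inst) %in% reg$name), 70)
  expect_true(all(inst$n_calls_in == 0))
  expect_true(all(is.na(inst[participant_id == pid, radius_of_gyration])))
  expect_true(all(is.na(inst[participant_id == pid, lat_mean])))
  # hour encoding is the prediction-time hour
  expect_true(all(inst$hour_of_day ==
                    hour_of_day(snap_epoch(prep$events$onset[match(inst$event_id,
                                  prep$events$event_id)]) - 3600)))
})
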