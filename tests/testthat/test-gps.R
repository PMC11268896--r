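# GPS pipeline: QC, thinning, sunrise, daily segmentation, and the three
# daily metrics.

test_that("quality filter applies strict Hdop and satellite boundaries", {
  f <- make_clean_fixes(n_days = 1, per_day = 12)
  f$hdop[3] <- 10.5                     # above the ceiling -> removed
  f$hdop[4] <- 10.0; f$n_satellites[4] <- 3   # both exactly at bound -> kept
  f$n_satellites[5] <- 2                # below the floor -> removed
  out <- filter_quality(f)
  qc <- attr(out, "qc")
  expect_equal(qc$removed_hdop, 1)
  expect_equal(qc$removed_satellites, 1)
  expect_equal(nrow(out), 10)
  expect_true(f$timestamp[4] %in% out$timestamp)

  # empty input -> empty output
  expect_equal(nrow(filter_quality(f[0, ])), 0)

  # missing metadata: retained and counted
  f2 <- make_clean_fixes(n_days = 1, per_day = 5)
  f2$hdop <- NA_real_
  out2 <- filter_quality(f2)
  expect_equal(nrow(out2), 5)
  expect_equal(attr(out2, "qc")$missing_hdop, 5)
})

test_that("quality filter removes duplicates and implied-speed outliers", {
  f <- make_clean_fixes(n_days = 1, per_day = 10)
  f <- rbind(f, f[4, ])                       # exact duplicate timestamp
  jump <- f[8, ]; jump$lat <- jump$lat + 1    # ~111 km in 0 s -> plant on later fix
  f$lat[8] <- f$lat[8] + 1                    # 111 km in 15 min ~ 123 m/s
  out <- filter_quality(f)
  qc <- attr(out, "qc")
  expect_equal(qc$removed_duplicate, 1)
  expect_equal(qc$removed_speed, 1)
})

test_that("filter and thinning are idempotent and order-safe", {
  set.seed(5)
  f <- make_clean_fixes(n_days = 2, per_day = 20)
  f$hdop[sample(40, 5)] <- 15
  strip <- function(d) { attr(d, "qc") <- NULL; rownames(d) <- NULL; d }
  once <- filter_quality(f)
  twice <- filter_quality(once)
  expect_equal(strip(once), strip(twice))
  t1 <- thin_min_interval(once)
  t2 <- thin_min_interval(t1)
  expect_equal(strip(t1), strip(t2))
  # shuffling rows changes nothing
  shuf <- filter_quality(f[sample(nrow(f)), ])
  expect_equal(strip(once), strip(shuf))
})

test_that("thinning keeps the greedy >= min-gap subsequence", {
  base <- as.POSIXct("2021-01-10 08:00:00", tz = "UTC")
  f <- data.frame(individual_id = "b", timestamp = base + c(0, 10, 20, 30) * 60,
                  lat = 43.8, lon = 4.0, stringsAsFactors = FALSE)
  out <- thin_min_interval(f, min_gap = 15)
  expect_equal(as.numeric(out$timestamp - base, units = "mins"), c(0, 20))
  # exact 15-min spacing: everything kept (boundary is >=)
  f2 <- data.frame(individual_id = "b", timestamp = base + (0:9) * 900,
                   lat = 43.8, lon = 4.0)
  expect_equal(nrow(thin_min_interval(f2)), 10)
  # single fix kept
  expect_equal(nrow(thin_min_interval(f2[1, ])), 1)
  # unordered input errors
  f3 <- f[c(2, 1, 3, 4), ]
  expect_error(thin_min_interval(f3), "ordered")
})

test_that("sunrise matches the independent NOAA-spreadsheet oracle", {
  # frozen oracle values from a Meeus-based implementation (minutes UTC)
  sr <- sunrise_utc(43.6, 3.9, as.Date("2020-06-21"))
  mins <- as.numeric(sr - as.POSIXct("2020-06-21", tz = "UTC"), units = "mins")
  expect_lt(abs(mins - 243.17), 2)
  # equatorial equinox: 06:00 UTC +/- 10 min at lon 0
  sr0 <- sunrise_utc(0, 0, as.Date("2020-03-20"))
  mins0 <- as.numeric(sr0 - as.POSIXct("2020-03-20", tz = "UTC"), units = "mins")
  expect_lt(abs(mins0 - 360), 10)
  # polar night errors
  expect_error(sunrise_utc(80, 0, as.Date("2020-12-21")), "66.5|polar")
})

test_that("daily segmentation applies the min-fix floor and the anchor window", {
  f <- make_clean_fixes(n_days = 2, per_day = 12)
  f9 <- make_clean_fixes(n_days = 1, per_day = 9, id = "b1",
                         start = as.POSIXct("2021-01-20 07:00:00", tz = "UTC"))
  tracks <- build_daily_tracks(rbind(f, f9), tz_offset = 1)
  expect_length(tracks, 2)           # the 9-fix day is dropped
  expect_equal(attr(tracks, "qc")$dropped_short_days, 1)

  # anchor window membership: first fix exactly at sunrise -> ok;
  # 121 min after -> not ok
  lat <- 43.8; lon <- 4.0
  d <- as.Date("2021-03-05")
  sr <- sunrise_utc(lat, lon, d)
  mk <- function(t0) data.frame(individual_id = "a", timestamp = t0 + (0:11) * 900,
                                lat = lat, lon = lon)
  tr_at <- build_daily_tracks(mk(sr), tz_offset = 1)
  expect_true(tr_at[[1]]$anchor_ok)
  tr_late <- build_daily_tracks(mk(sr + 121 * 60), tz_offset = 1)
  expect_false(tr_late[[1]]$anchor_ok)
  tr_before <- build_daily_tracks(mk(sr - 30 * 60), tz_offset = 1)
  expect_true(tr_before[[1]]$anchor_ok)
})

test_that("segment speeds use great-circle distance and the max-of-adjacent rule", {
  lat0 <- 43.8; lon0 <- 4.0
  # two fixes 2700 m apart in 900 s: exactly 3 m/s -> NOT in flight (strict >)
  p <- step_ll(lat0, lon0, 90, 2700)
  tr <- make_track(c(lat0, p[1]), c(lon0, p[2]))
  sp <- segment_speeds(tr)
  expect_equal(sp, c(3, 3), tolerance = 1e-4)
  m <- compute_daily_metrics(tr)
  expect_equal(m$k_flight, 0)

  # identical coordinates -> 0 speed
  tr0 <- make_track(c(lat0, lat0), c(lon0, lon0))
  expect_equal(segment_speeds(tr0), c(0, 0))

  # three collinear fixes with segment speeds {2, 4} -> fix speeds {2, 4, 4}
  p1 <- step_ll(lat0, lon0, 90, 2 * 900)
  p2 <- step_ll(p1[1], p1[2], 90, 4 * 900)
  tr3 <- make_track(c(lat0, p1[1], p2[1]), c(lon0, p1[2], p2[2]))
  expect_equal(segment_speeds(tr3, "max"), c(2, 4, 4), tolerance = 1e-3)
  expect_equal(segment_speeds(tr3, "mean"), c(2, 3, 4), tolerance = 1e-3)
  expect_equal(segment_speeds(tr3, "forward"), c(2, 4, 4), tolerance = 1e-3)
})

test_that("daily range is the anchor-excluded median and respects anchor_ok", {
  lat0 <- 43.8; lon0 <- 4.0
  mk_dist_track <- function(dists) {
    pts <- t(vapply(dists, function(d) step_ll(lat0, lon0, 90, d), c(1, 1)))
    make_track(c(lat0, pts[, 1]), c(lon0, pts[, 2]))
  }
  # even-length non-anchor set {100,200,300,400} -> 250
  expect_equal(daily_range(mk_dist_track(c(100, 200, 300, 400))), 250,
               tolerance = 0.5)
  # odd-length {100,200,300} -> 200
  expect_equal(daily_range(mk_dist_track(c(100, 200, 300))), 200,
               tolerance = 0.5)
  # all fixes at the anchor -> 0
  expect_equal(daily_range(make_track(rep(lat0, 5), rep(lon0, 5))), 0)
  # anchor rule failed -> absent, not zero
  tr <- mk_dist_track(c(100, 200, 300))
  tr$anchor_ok <- FALSE
  expect_true(is.na(daily_range(tr)))
})

test_that("straightness is D/L with the documented edge cases", {
  lat0 <- 43.8; lon0 <- 4.0
  # equally spaced collinear eastward fixes -> 1
  pts <- t(vapply(0:4 * 500, function(d) step_ll(lat0, lon0, 90, d), c(1, 1)))
  expect_equal(straightness(make_track(pts[, 1], pts[, 2])), 1,
               tolerance = 1e-6)
  # closed loop -> 0
  sq <- rbind(c(lat0, lon0),
              step_ll(lat0, lon0, 0, 500),
              step_ll(step_ll(lat0, lon0, 0, 500)[1],
                      step_ll(lat0, lon0, 0, 500)[2], 90, 500),
              step_ll(lat0, lon0, 90, 500),
              c(lat0, lon0))
  expect_lt(straightness(make_track(sq[, 1], sq[, 2])), 1e-6)
  # right angle (0,0) -> (0,1km) -> (1km,1km): D/L = sqrt(2)/2
  a <- step_ll(lat0, lon0, 0, 1000)
  b <- step_ll(a[1], a[2], 90, 1000)
  tr <- make_track(c(lat0, a[1], b[1]), c(lon0, a[2], b[2]))
  expect_equal(straightness(tr), sqrt(2) / 2, tolerance = 1e-3)
  # fully stationary day -> NA
  expect_true(is.na(straightness(make_track(rep(lat0, 4), rep(lon0, 4)))))
})

test_that("haversine agrees with the Vincenty ellipsoidal oracle at study scales", {
  set.seed(77)
  for (i in 1:100) {
    lat1 <- runif(1, 42.5, 44.5); lon1 <- runif(1, 2.5, 6.5)
    brg <- runif(1, 0, 360); d <- runif(1, 50, 50000)
    p <- step_ll(lat1, lon1, brg, d)
    hv <- haversine_m(lat1, lon1, p[1], p[2])
    vc <- vincenty_m(lat1, lon1, p[1], p[2])
    expect_lt(abs(hv - vc) / vc, 0.005)
  }
})

test_that("metric bounds hold across simulated days and truth matches at zero noise", {
  cfg <- test_sim_config(
    movement_params = list(gps_noise_sd_m = 0),
    qc_violation_rates = list(hdop = 0, satellites = 0, short_day = 0,
                              anchor = 0))
  pop <- simulate_population(cfg)
  cells <- make_weather_cells(pop$nests$lat, pop$nests$lon)
  dates <- seq(as.Date("2018-12-01"), by = "day", length.out = 40)
  wx <- simulate_weather(dates[1], 40, cells, cfg$weather_params, 5)
  tr <- simulate_tracks(pop$individuals[1, ], pop$nests, 5, dates, wx, cells,
                        cfg, 99)
  met <- preprocess_tracks(tr$fixes)
  expect_true(all(met$prop_flight >= 0 & met$prop_flight <= 1))
  expect_true(all(met$straightness >= 0 & met$straightness <= 1, na.rm = TRUE))
  expect_true(all(met$range_m >= 0, na.rm = TRUE))
  expect_equal(met$prop_flight, met$k_flight / met$n_fixes)
  td <- tr$truth$days
  i <- match(paste(met$individual_id, met$date),
             paste(td$individual_id, td$date))
  expect_equal(met$k_flight, td$k_flight[i])
  expect_equal(met$n_fixes, td$n_fixes[i])
})

test_that("anchor_global and daylight_only options behave as documented", {
  lat <- 43.8; lon <- 4.0
  d <- as.Date("2021-03-05")
  sr <- sunrise_utc(lat, lon, d)
  # sunset is after sunrise and roughly mirrors it about solar noon
  ss <- sunset_utc(lat, lon, d)
  expect_gt(as.numeric(ss - sr, units = "hours"), 8)
  expect_lt(as.numeric(ss - sr, units = "hours"), 14)

  mk <- function(t0, id) data.frame(individual_id = id,
                                    timestamp = t0 + (0:11) * 900,
                                    lat = lat, lon = lon + (0:11) * 1e-4)
  f <- rbind(mk(sr, "ok"), mk(sr + 180 * 60, "late"))
  all_days <- preprocess_tracks(f)
  expect_equal(nrow(all_days), 2)
  expect_true(is.na(all_days$range_m[all_days$individual_id == "late"]))
  only_anchored <- preprocess_tracks(f, anchor_global = TRUE)
  expect_equal(only_anchored$individual_id, "ok")

  # fixes planted after sunset vanish under daylight_only
  night <- data.frame(individual_id = "ok",
                      timestamp = ss + (1:3) * 3600,
                      lat = lat, lon = lon + 0.02)
  f2 <- rbind(mk(sr, "ok"), night)
  m_all <- preprocess_tracks(f2)
  m_day <- preprocess_tracks(f2, daylight_only = TRUE)
  expect_gt(m_all$n_fixes, m_day$n_fixes)
  expect_equal(m_day$n_fixes, 12)
})

test_that("straightness separates out-and-back from one-way transit days", {
  lat0 <- 43.8; lon0 <- 4.0
  # out-and-back: 10 fixes out east, 10 back
  out <- t(vapply(c(0:9, 8:0) * 400, function(d) step_ll(lat0, lon0, 90, d),
                  c(1, 1)))
  expect_lt(straightness(make_track(out[, 1], out[, 2])), 0.1)
  # one-way transit
  tw <- t(vapply(0:19 * 400, function(d) step_ll(lat0, lon0, 45, d), c(1, 1)))
  expect_gt(straightness(make_track(tw[, 1], tw[, 2])), 0.9)
})
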