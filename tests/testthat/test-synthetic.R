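# Synthetic-data generators: determinism, distributional recovery, staging
# and label/speed consistency.

test_that("config validation rejects bad probabilities, scales and levels", {
  expect_error(sim_config(weather_params = list(wet_p = 1.3)), "probabilities")
  expect_error(sim_config(weather_params = list(rain_scale = -1)), "scale")
  expect_error(sim_config(recruitment_freqs = c("0" = 0.5, F = 0.5, M = 0.2,
                                                MF = -0.2)), "probabilities")
  expect_error(sim_config(recruitment_freqs = c(A = 1)), "0/F/M/MF")
  expect_error(sim_config(movement_params = list(flight_speed_min = 2)),
               "exceed 3")
  expect_error(sim_config(weather_params = list(bogus = 1)), "unknown config key")
})

test_that("weather simulation is deterministic and respects construction", {
  cells <- data.frame(cell_id = c("a", "b"))
  p <- sim_config()$weather_params
  w1 <- simulate_weather(as.Date("2020-12-01"), 50, cells, p, 123)
  w2 <- simulate_weather(as.Date("2020-12-01"), 50, cells, p, 123)
  expect_identical(w1, w2)
  w3 <- simulate_weather(as.Date("2020-12-01"), 50, cells, p, 124)
  expect_false(identical(w1, w3))
  expect_true(all(w1$rain_mm >= 0))
  expect_true(all(w1$wind_ms >= 0))
  expect_equal(nrow(w1), 100)                 # one record per cell-day
  expect_false(anyDuplicated(w1[c("cell_id", "date")]) > 0)
  expect_error(simulate_weather(as.Date("2020-12-01"), 0, cells, p, 1), "n_days")
})

test_that("weather moments match the configured generating values", {
  cells <- data.frame(cell_id = "a")
  p <- sim_config(weather_params = list(wet_p = 0.2))$weather_params
  w <- simulate_weather(as.Date("2000-01-01"), 10000, cells, p, 7)
  # wet-day frequency within the binomial bound
  expect_lt(abs(mean(w$rain_mm > 0) - 0.2), 0.02)
  # wind mean
  expect_lt(abs(mean(w$wind_ms) - p$wind_mean), 3 * sd(w$wind_ms) / 100)
  # wet-day rain mean = shape * scale
  wet <- w$rain_mm[w$rain_mm > 0]
  expect_lt(abs(mean(wet) - p$rain_shape * p$rain_scale),
            3 * sd(wet) / sqrt(length(wet)))
})

test_that("population: pairs, experience domain and recruitment frequencies", {
  cfg <- sim_config(n_sites = 0)
  pop0 <- simulate_population(cfg)
  expect_equal(nrow(pop0$events), 0)
  expect_equal(nrow(pop0$individuals), 0)

  # frequencies over ~5000 events
  cfg <- sim_config(n_sites = 100, n_years = 50, seed = 8)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$events), 5000)
  expect_true(all(pop$events$male_experience %in% 1:15))
  expect_true(all(pop$events$female_experience %in% 1:15))
  obs <- table(factor(pop$events$recruitment,
                      levels = names(cfg$recruitment_freqs))) / 5000
  for (lv in names(cfg$recruitment_freqs)) {
    expect_lt(abs(obs[[lv]] - cfg$recruitment_freqs[[lv]]), 0.02)
  }
  # a recruited member always restarts at experience 1
  rec_m <- pop$events$recruitment %in% c("M", "MF") &
    pop$events$year > min(pop$events$year)
  expect_true(all(pop$events$male_experience[rec_m] == 1))
})

test_that("track generator: determinism, intercept-only flight fraction, radius", {
  cfg <- sim_config(
    n_sites = 1, n_years = 1, seed = 2,
    behaviour_coefs = list(intercept = 0, rain = 0, temp = 0, wind2 = 0,
                           experience = 0, individual_sd = 0),
    qc_violation_rates = list(hdop = 0, satellites = 0, short_day = 0,
                              anchor = 0))
  pop <- simulate_population(cfg)
  cells <- make_weather_cells(pop$nests$lat, pop$nests$lon)
  dates <- seq(as.Date("2019-01-01"), by = "day", length.out = 120)
  wx <- simulate_weather(dates[1], 120, cells, cfg$weather_params, 4)
  ind <- pop$individuals[1, ]
  tr1 <- simulate_tracks(ind, pop$nests, 5, dates, wx, cells, cfg, 31)
  tr2 <- simulate_tracks(ind, pop$nests, 5, dates, wx, cells, cfg, 31)
  expect_identical(tr1, tr2)

  # all-zero coefficients: non-anchor fix-level flight fraction -> 0.5
  td <- tr1$truth$days
  expect_true(all(abs(td$p_flight - 0.5) < 1e-12))
  frac <- sum(td$k_flight) / sum(td$n_fixes - 1)
  mc <- 3 * sqrt(0.25 / sum(td$n_fixes - 1)) + 0.01  # + run-rounding slack
  expect_lt(abs(frac - 0.5), mc + 0.02)

  # every fix within the excursion radius (+ noise allowance)
  nest <- pop$nests[1, ]
  dmax <- max(haversine_m(nest$lat, nest$lon, tr1$fixes$lat, tr1$fixes$lon))
  expect_lt(dmax, cfg$movement_params$excursion_radius_m +
              5 * cfg$movement_params$gps_noise_sd_m + 1)

  # missing weather day errors naming the date
  expect_error(simulate_tracks(ind, pop$nests, 5, dates, wx[wx$date != dates[5], ],
                               cells, cfg, 31), format(dates[5]))
})

test_that("flight labels and displacement speeds agree", {
  cfg <- test_sim_config(qc_violation_rates = list(hdop = 0, satellites = 0,
                                                   short_day = 0, anchor = 0))
  pop <- simulate_population(cfg)
  cells <- make_weather_cells(pop$nests$lat, pop$nests$lon)
  dates <- seq(as.Date("2019-02-01"), by = "day", length.out = 60)
  wx <- simulate_weather(dates[1], 60, cells, cfg$weather_params, 9)
  tr <- simulate_tracks(pop$individuals[1, ], pop$nests, 7, dates, wx, cells,
                        cfg, 55)
  f <- tr$fixes; lab <- tr$truth$labels
  ok <- 0; tot <- 0
  for (dd in unique(as.Date(f$timestamp + 3600, tz = "UTC"))) {
    i <- which(as.Date(f$timestamp + 3600, tz = "UTC") == dd)
    if (length(i) < 2) next
    d <- haversine_m(f$lat[i][-length(i)], f$lon[i][-length(i)],
                     f$lat[i][-1], f$lon[i][-1])
    sp <- d / diff(as.numeric(f$timestamp[i]))
    both_flight <- lab[i][-length(i)] == "flight" & lab[i][-1] == "flight"
    tot <- tot + sum(both_flight)
    ok <- ok + sum(both_flight & sp > 3)
  }
  expect_gt(tot, 50)
  expect_gte(ok / tot, 0.99)
})

test_that("breeding: staging, degenerate probabilities and frequency recovery", {
  cfg <- sim_config(seed = 3)
  ev <- data.frame(site_id = "s", year = 2020,
                   recruitment = rep(c("0", "F", "M", "MF"), each = 1250),
                   stringsAsFactors = FALSE)
  out <- simulate_breeding(ev, config = cfg, seed = 10)
  expect_silent(validate_breeding_events(out))
  # fledgling count 0 exactly when not fledged; never when not laid
  expect_true(all(out$n_fledged[!out$laid] == 0))
  expect_true(all(out$n_fledged[!is.na(out$fledged) & out$fledged] > 0))

  # MF laying frequency ~ 0.46 over 1250 events (3-sigma binomial bound)
  mf <- out$laid[out$recruitment == "MF"]
  expect_lt(abs(mean(mf) - 0.46), 3 * sqrt(0.46 * 0.54 / length(mf)))
  # level-0 frequency ~ 0.95
  l0 <- out$laid[out$recruitment == "0"]
  expect_lt(abs(mean(l0) - 0.95), 3 * sqrt(0.95 * 0.05 / length(l0)))

  # all stage probabilities 1 -> every event fledges at least one chick
  cfg1 <- sim_config(breeding_coefs = list(
    p_lay = c("0" = 1, "F" = 1, "M" = 1, "MF" = 1), p_hatch = 1, p_fledge = 1,
    tmax_slope_hatch = 0, tmax_slope_fledge = 0))
  out1 <- simulate_breeding(ev, config = cfg1, seed = 10)
  expect_true(all(out1$n_fledged >= 1))

  expect_error(simulate_breeding(data.frame(recruitment = "X"), config = cfg,
                                 seed = 1), "unknown recruitment")
})

test_that("productivity link: recovered slope matches the configured -0.26", {
  cfg <- sim_config(seed = 6)
  bc <- cfg$breeding_coefs
  # the generator calibrates its clamped second-chick mechanism so the
  # population least-squares slope of E[count] on z ~ N(0,1) equals the
  # configured value; recover it with plain regression over replicates
  reps <- 60; n_ev <- 200
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(4000 + r)
    ev <- data.frame(site_id = sample(sprintf("s%02d", 1:20), n_ev, TRUE),
                     year = 2020,
                     recruitment = sample(c("0", "F", "M", "MF"), n_ev, TRUE,
                                          c(0.7, 0.12, 0.12, 0.06)),
                     stringsAsFactors = FALSE)
    mf <- rnorm(n_ev)
    out <- simulate_breeding(ev, male_rearing_flight = mf, config = cfg,
                             seed = 4000 + r)
    est[r] <- coef(lm(out$n_fledged ~ scale(mf)))[2]
  }
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - bc$male_flight_slope), 3 * mc_se)
})

test_that("simulate_dataset is deterministic and internally consistent", {
  cfg <- test_sim_config(tracked_fraction = 0.5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$fixes, d2$fixes)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$weather, d2$weather)
  expect_silent(validate_breeding_events(d1$events))
  # every tracked bird has fixes; untracked have none
  tracked <- d1$individuals$individual_id[d1$individuals$tracked]
  expect_setequal(unique(d1$fixes$individual_id), tracked)
  # CSV round trip of the tracking table
  dir <- withr::local_tempdir()
  write_dataset_csv(d1, dir)
  back <- read_tracks(file.path(dir, "tracks.csv"))
  expect_equal(nrow(back), nrow(d1$fixes))
  i <- order(d1$fixes$individual_id, d1$fixes$timestamp)
  expect_equal(back$lat, d1$fixes$lat[i], tolerance = 1e-9)
  expect_equal(as.numeric(back$timestamp), as.numeric(d1$fixes$timestamp[i]))
})
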