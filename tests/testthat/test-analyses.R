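# Analysis battery: descriptive tables, phase/sex comparison, movement,
# breeding and productivity models.

# shared: fast daily movement table straight from the latent day model
# (weather draws i.i.d. per bird-day; individual intercept sd as configured)
sim_daily_movement <- function(n_birds, n_days, cfg, seed, sexes = "M",
                               phase = "incubation") {
  set.seed(seed)
  bc <- cfg$behaviour_coefs
  wp <- cfg$weather_params
  rows <- vector("list", n_birds)
  for (b in seq_len(n_birds)) {
    rain <- rbinom(n_days, 1, wp$wet_p) *
      rgamma(n_days, wp$rain_shape, scale = wp$rain_scale)
    wind <- rgamma(n_days, wp$wind_shape, scale = wp$wind_mean / wp$wind_shape)
    temp <- rnorm(n_days, 9, 3)
    ex <- sample(1:15, 1)
    u <- rnorm(1, 0, bc$individual_sd)
    lp <- bc$intercept + u + bc$rain * rain + bc$temp * (temp - bc$temp_ref) +
      bc$wind2 * (wind - bc$wind_opt)^2 + bc$experience * (ex - bc$exp_ref)
    n_f <- 1 + rpois(n_days, cfg$fixes_per_day$mean - 1)
    k <- rbinom(n_days, n_f - 1, plogis(lp))
    rows[[b]] <- data.frame(
      individual_id = sprintf("b%03d", b),
      sex = sexes[1 + (b %% length(sexes))], phase = phase,
      k_flight = k, n_fixes = n_f,
      range_m = exp(7 + 0.3 * rnorm(n_days)),
      straightness = plogis(rnorm(n_days, -2, 0.8)),
      experience = ex, rain = rain, temp = temp, wind = wind,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("descriptive table: hand-checked stats and CV definition", {
  pm <- data.frame(individual_id = c("a", "b", "c"), sex = "M",
                   phase = "incubation",
                   prop_flight = c(1, 2, 3) / 10,
                   range_m = c(1000, 1000, 1000),
                   straightness = c(0.1, 0.2, 0.3), n_days = 5)
  tab <- descriptive_table(pm)
  r <- tab[tab$period == "incubation" & tab$metric == "prop_flight", ]
  expect_equal(r$mean, 0.2)
  expect_equal(r$sd, 0.1)                      # sample SD (n-1)
  expect_equal(r$cv_pct, 50)                   # 100 * SD / mean
  r2 <- tab[tab$period == "incubation" & tab$metric == "range_m", ]
  expect_equal(r2$sd, 0)
  expect_equal(r2$cv_pct, 0)
  expect_true(all(tab$min <= tab$mean & tab$mean <= tab$max))
})

test_that("phase means respect daily-metric bounds and count days", {
  cfg <- test_sim_config()
  d <- sim_daily_movement(4, 20, cfg, 31)
  d$date <- rep(seq(as.Date("2021-03-05"), by = "day", length.out = 20), 4)
  d$prop_flight <- d$k_flight / d$n_fixes
  w <- phase_windows(2021); w$year <- 2021
  pm <- phase_means(d, w)
  expect_true(all(pm$prop_flight >= 0 & pm$prop_flight <= 1))
  expect_true(all(pm$n_days == 20))
  expect_equal(sort(unique(pm$phase)), "incubation")
})

test_that("phase/sex comparison recovers a planted incubation contrast", {
  set.seed(61)
  birds <- sprintf("i%02d", 1:40)
  sex <- rep(c("M", "F"), 20)
  rows <- list()
  for (i in seq_along(birds)) for (ph in c("pre-breeding", "incubation", "rearing")) {
    mu <- 0.25
    if (ph == "incubation" && sex[i] == "F") mu <- 0.25 * 0.7  # 30% lower
    rows[[length(rows) + 1]] <- data.frame(
      individual_id = birds[i], sex = sex[i], phase = ph,
      prop_flight = max(0.01, rnorm(1, mu, 0.03)),
      range_m = exp(rnorm(1, 7.5, 0.3)),
      straightness = plogis(rnorm(1, -2, 0.3)), n_days = 30)
  }
  pm <- do.call(rbind, rows)
  cmp <- phase_sex_comparison(pm)
  w <- wald_summary(cmp$fits$prop_flight)
  # the sex x incubation interaction is the planted signal
  i_int <- grep("sexM:phaseincubation", w$term)
  expect_equal(w$tag[i_int], "significant")
  expect_gt(w$estimate[i_int], 0)    # males higher than females in incubation
  # cell means reproduce the planted pattern
  cm <- cmp$cell_means
  f_inc <- cm$estimate[cm$metric == "prop_flight" & cm$sex == "F" &
                         cm$phase == "incubation"]
  m_inc <- cm$estimate[cm$metric == "prop_flight" & cm$sex == "M" &
                         cm$phase == "incubation"]
  expect_lt(f_inc, m_inc)
  expect_error(phase_sex_comparison(pm[pm$phase == "incubation", ]),
               ">= 2 phases")
})

test_that("movement battery recovers planted covariate effects", {
  cfg <- sim_config(seed = 3)
  d <- sim_daily_movement(25, 80, cfg, 71)
  fits <- fit_movement_models(d)
  fit <- fits[["M.incubation"]]$flight
  braw <- coef_raw(fit)
  expect_lt(abs(braw[["rain"]] - cfg$behaviour_coefs$rain), 0.06)
  expect_gt(wind_vertex(fit), 4.5); expect_lt(wind_vertex(fit), 5.5)
  w <- wald_summary(fit)
  expect_equal(w$tag[w$term == "rain"], "significant")
  # tidy table carries every converged fit
  expect_true(all(c("M.incubation.flight", "M.incubation.range",
                    "M.incubation.straightness") %in% fits$coefficients$model))
  # a one-individual cell is skipped with a warning
  d1 <- d[d$individual_id %in% unique(d$individual_id)[1], ]
  expect_warning(fit_movement_models(d1), "< 2 individuals")
})

test_that("straightness logit nudge handles exact 0/1 without error", {
  cfg <- sim_config(seed = 3)
  d <- sim_daily_movement(6, 30, cfg, 73)
  d$straightness[1:5] <- 0
  d$straightness[6:10] <- 1
  expect_silent(suppressWarnings(fits <- fit_movement_models(d)))
  expect_true(is.finite(fits[["M.incubation"]]$straightness$loglik))
})

test_that("breeding models: staging validation, level drop, type-I sanity", {
  bad <- data.frame(site_id = "s", year = 2020, recruitment = "0",
                    laid = FALSE, hatched = TRUE, fledged = NA,
                    n_fledged = 0L)
  expect_error(validate_breeding_events(bad), "hatched without laid")
  bad2 <- data.frame(site_id = "s", year = 2020, recruitment = "0",
                     laid = TRUE, hatched = TRUE, fledged = TRUE,
                     n_fledged = 3L)
  expect_error(validate_breeding_events(bad2), "0, 1, 2")

  # small but fittable battery on generator output
  cfg <- sim_config(seed = 13)
  set.seed(13)
  sites <- sprintf("s%02d", 1:25)
  ev <- expand.grid(site_id = sites, year = 2015:2020, stringsAsFactors = FALSE)
  ev$recruitment <- sample(c("0", "F", "M"), nrow(ev), TRUE, c(0.76, 0.12, 0.12))
  ev$tmax_z_incubation <- rnorm(nrow(ev))
  ev$tmax_z_rearing <- rnorm(nrow(ev))
  out <- simulate_breeding(ev, config = cfg, seed = 14)
  pw <- expand.grid(site_id = sites, year = 2015:2020,
                    phase = c("pre-breeding", "incubation", "rearing"),
                    stringsAsFactors = FALSE)
  set.seed(15)
  pw$rain_cum_mm <- rgamma(nrow(pw), 4, scale = 30)
  pw$temp_min_c <- rnorm(nrow(pw), 2, 2)
  pw$temp_max_c <- rnorm(nrow(pw), 18, 2)
  pw$days_wind_above <- rbinom(nrow(pw), 30, 0.15)
  pw$days_wind_below <- rbinom(nrow(pw), 30, 0.2)
  ws <- capture_warnings(bm <- fit_breeding_models(out, pw))
  expect_true(any(grepl("MF absent", ws)))
  expect_equal(nrow(bm$predicted_laying), 3)
  expect_true(all(bm$predicted_laying$probability > 0 &
                    bm$predicted_laying$probability < 1))
  # hatching rows are a subset of laid events
  expect_lte(bm$hatching$nobs, sum(out$laid))
})

test_that("standardization is recomputed per model dataset", {
  cfg <- sim_config(seed = 3)
  d <- sim_daily_movement(12, 40, cfg, 91)
  full <- fit_binomial_glmm(cbind(k_flight, n_fixes - k_flight) ~ rain + wind,
                            d, "individual_id")
  sub <- d[d$rain > median(d$rain), ]
  refit <- fit_binomial_glmm(cbind(k_flight, n_fixes - k_flight) ~ rain + wind,
                             sub, "individual_id")
  expect_false(isTRUE(all.equal(full$standardizers$rain$mean,
                                refit$standardizers$rain$mean)))
})

test_that("productivity battery wiring: full-season subset and domains", {
  cfg <- sim_config(seed = 5)
  set.seed(95)
  birds <- sprintf("m%02d", 1:20)
  pm <- do.call(rbind, lapply(birds, function(b) {
    data.frame(individual_id = b, sex = "M",
               phase = c("pre-breeding", "incubation", "rearing"),
               prop_flight = runif(3, 0.1, 0.4),
               range_m = exp(rnorm(3, 7.5, 0.4)),
               straightness = runif(3, 0.02, 0.3), n_days = 25)
  }))
  # one bird missing a phase -> excluded from the subset
  pm <- pm[!(pm$individual_id == "m01" & pm$phase == "rearing"), ]
  ev <- data.frame(site_id = sample(sprintf("s%d", 1:8), 20, TRUE),
                   year = 2020, recruitment = "0", male_id = birds,
                   female_id = NA, laid = TRUE, hatched = TRUE,
                   fledged = TRUE, n_fledged = sample(1:2, 20, TRUE))
  suppressWarnings(fits <- fit_productivity_models(pm, ev))
  f <- fits[["M.rearing.prop_flight"]]
  expect_false("m01" %in% rownames(f))   # wiring only; m01 had no full season
  expect_equal(f$nobs, 19)
  # n_fledged outside {0,1,2} rejected
  ev$n_fledged[1] <- 3L
  expect_error(fit_productivity_models(pm, ev), "0, 1, 2")
})

test_that("null weather effects are tagged significant at ~ the nominal rate", {
  # scaled null check on the movement flight model: rain/temp slopes zero
  cfg <- sim_config(seed = 1, behaviour_coefs = list(
    rain = 0, temp = 0, wind2 = 0, experience = 0))
  reps <- 30; hits <- 0; terms <- 0
  for (r in seq_len(reps)) {
    d <- sim_daily_movement(12, 40, cfg, 7000 + r)
    fit <- fit_binomial_glmm(cbind(k_flight, n_fixes - k_flight) ~ rain + temp,
                             d, "individual_id")
    if (!fit$converged) next
    w <- wald_summary(fit)
    hits <- hits + sum(w$tag[w$term %in% c("rain", "temp")] == "significant")
    terms <- terms + 2
  }
  expect_lte(hits / terms, 0.15)   # ~5% nominal; wide band at 30 reps
})
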