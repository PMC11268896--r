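# Shared fixture builders. Everything is generated in code; no data files.

# a clean fix table: one bird, `n_days` days of `per_day` fixes at 15-min
# spacing starting 07:00 UTC, walking slowly east (all speeds < 1 m/s)
make_clean_fixes <- function(n_days = 3, per_day = 15, id = "b1",
                             lat0 = 43.8, lon0 = 4.0,
                             start = as.POSIXct("2021-01-10 07:00:00", tz = "UTC")) {
  rows <- list()
  for (d in seq_len(n_days)) {
    tt <- start + (d - 1) * 86400 + (seq_len(per_day) - 1) * 900
    rows[[d]] <- data.frame(
      individual_id = id, timestamp = tt,
      lat = lat0, lon = lon0 + (seq_len(per_day) - 1) * 1e-4,
      hdop = 2, n_satellites = 8, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# a cpf_track straight from coordinate vectors (bypasses QC for metric tests)
make_track <- function(lat, lon, minutes = (seq_along(lat) - 1) * 15,
                       anchor_ok = TRUE, id = "t1",
                       date = as.Date("2021-03-01")) {
  ts <- as.POSIXct(paste(date, "07:00:00"), tz = "UTC") + minutes * 60
  structure(list(
    individual_id = id, date = date,
    fixes = data.frame(individual_id = id, timestamp = ts,
                       lat = lat, lon = lon, stringsAsFactors = FALSE),
    sunrise = ts[1], anchor_ok = anchor_ok, n_fixes = length(lat)
  ), class = "cpf_track")
}

# move `dist_m` metres from (lat, lon) at bearing `brg` (degrees)
step_ll <- function(lat, lon, brg, dist_m) {
  p <- cpforager::unproject_tmerc(sin(brg * pi / 180) * dist_m,
                                  cos(brg * pi / 180) * dist_m, lat, lon)
  c(p$lat, p$lon)
}

# balanced one-way random-effects data: a groups x n reps
make_oneway <- function(a = 10, n = 6, mu = 3, su = 1.2, se = 0.8, seed = 1) {
  set.seed(seed)
  g <- rep(seq_len(a), each = n)
  data.frame(y = mu + rep(rnorm(a, 0, su), each = n) + rnorm(a * n, 0, se),
             g = g)
}

# grouped binomial data for GLMM tests
make_binom_groups <- function(G = 5, m = 10, beta = c(-0.5, 0.8), su = 0.7,
                              seed = 3, trials = 20) {
  set.seed(seed)
  g <- rep(seq_len(G), each = m)
  x <- rnorm(G * m)
  ntr <- stats::rpois(G * m, trials) + 1
  eta <- beta[1] + beta[2] * x + rep(rnorm(G, 0, su), each = m)
  data.frame(k = rbinom(G * m, ntr, stats::plogis(eta)), ntr = ntr,
             x = x, g = g)
}

# independent brute-force marginal log-likelihood (trapezoid rule over the
# random intercept), kept free of any package internals
trapezoid_loglik <- function(dat, beta, su, npts = 2001) {
  eta0 <- beta[1] + beta[2] * dat$x
  half <- 8 * max(su, 0.5) + 2
  bgrid <- seq(-half, half, length.out = npts)
  h <- diff(bgrid[1:2])
  total <- sum(lchoose(dat$ntr, dat$k))
  for (idx in split(seq_len(nrow(dat)), dat$g)) {
    lv <- vapply(bgrid, function(b0) {
      e <- eta0[idx] + b0
      sum(dat$k[idx] * e - dat$ntr[idx] * log1p(exp(e))) +
        stats::dnorm(b0, 0, su, log = TRUE)
    }, 1)
    mx <- max(lv)
    w <- exp(lv - mx)
    total <- total + mx + log((sum(w) - (w[1] + w[npts]) / 2) * h)
  }
  total
}

# Vincenty inverse distance on the WGS84 ellipsoid: the independent
# high-precision oracle for the haversine routine
vincenty_m <- function(lat1, lon1, lat2, lon2) {
  a <- 6378137; b <- 6356752.314245; f <- 1 / 298.257223563
  p <- pi / 180
  L <- (lon2 - lon1) * p
  U1 <- atan((1 - f) * tan(lat1 * p)); U2 <- atan((1 - f) * tan(lat2 * p))
  sU1 <- sin(U1); cU1 <- cos(U1); sU2 <- sin(U2); cU2 <- cos(U2)
  lam <- L
  for (i in 1:200) {
    sl <- sin(lam); cl <- cos(lam)
    ss <- sqrt((cU2 * sl)^2 + (cU1 * sU2 - sU1 * cU2 * cl)^2)
    if (ss == 0) return(0)
    cs <- sU1 * sU2 + cU1 * cU2 * cl
    sig <- atan2(ss, cs)
    sa <- cU1 * cU2 * sl / ss
    c2a <- 1 - sa^2
    c2m <- if (c2a == 0) 0 else cs - 2 * sU1 * sU2 / c2a
    C <- f / 16 * c2a * (4 + f * (4 - 3 * c2a))
    lam_new <- L + (1 - C) * f * sa *
      (sig + C * ss * (c2m + C * cs * (-1 + 2 * c2m^2)))
    if (abs(lam_new - lam) < 1e-12) { lam <- lam_new; break }
    lam <- lam_new
  }
  u2 <- c2a * (a^2 - b^2) / b^2
  A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
  B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))
  dsig <- B * ss * (c2m + B / 4 * (cs * (-1 + 2 * c2m^2) -
           B / 6 * c2m * (-3 + 4 * ss^2) * (-3 + 4 * c2m^2)))
  b * A * (sig - dsig)
}

# small standard sim config for tests (fast but structurally complete)
test_sim_config <- function(...) {
  args <- list(n_sites = 2, n_years = 1, seed = 42)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}
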