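# GPS track simulation for one individual-season.
#
# Day level: a latent flight probability p from the logit-linear weather /
# experience model (quadratic wind response with a configured optimum).
# Fix level: the day's flight fixes are allocated as contiguous runs of
# length >= 2 so that displacement-based speed classification reproduces the
# truth labels exactly at zero GPS noise: the bird moves only on segments
# whose BOTH endpoints are flight fixes, at a speed drawn above the 3 m/s
# threshold, as out-and-back excursion legs along a per-day bearing through
# the nest; perch fixes are stationary away from the nest, rest fixes sit at
# the nest. The first fix of a day is the nest anchor near sunrise.

# split k flight fixes into run lengths >= 2 (a leftover of 1 is absorbed)
flight_run_lengths <- function(k) {
  if (k < 2) return(integer(0))
  lens <- integer(0)
  rem <- k
  while (rem > 0) {
    len <- sample(2:6, 1)
    if (rem - len == 1) len <- len + 1
    len <- min(len, rem)
    if (len == 1) { lens[length(lens)] <- lens[length(lens)] + 1; break }
    lens <- c(lens, len)
    rem <- rem - len
  }
  lens
}

# place runs among positions 2..n with >= 1 non-flight fix between runs;
# returns logical flight indicator of length n (position 1 always FALSE)
place_runs <- function(n, lens) {
  z <- rep(FALSE, n)
  if (length(lens) == 0) return(z)
  slots <- n - 1
  while (length(lens) > 1 && sum(lens) + (length(lens) - 1) > slots) {
    # merge the two shortest runs when separators do not fit
    o <- order(lens)
    lens[o[1]] <- lens[o[1]] + lens[o[2]]
    lens <- lens[-o[2]]
  }
  lens <- lens[lens <= slots]
  if (length(lens) == 0) return(z)
  R <- length(lens)
  free <- slots - sum(lens) - (R - 1)
  extra <- if (free > 0) {
    stats::rmultinom(1, free, rep(1, R + 1))[, 1]
  } else rep(0, R + 1)
  pos <- 2
  for (r in seq_len(R)) {
    pos <- pos + extra[r] + if (r > 1) 1 else 0
    z[pos:(pos + lens[r] - 1)] <- TRUE
    pos <- pos + lens[r]
  }
  z
}

# simulate one day's fix positions (planar metres around the nest at 0,0)
simulate_day_positions <- function(z, dt_s, mp) {
  n <- length(z)
  xs <- numeric(n); ys <- numeric(n)
  if (n < 2) return(cbind(xs, ys))
  bearing <- stats::runif(1, 0, 2 * pi)
  ux <- cos(bearing); uy <- sin(bearing)
  r <- 0            # signed position along the bearing line through the nest
  dir <- 1
  for (j in 2:n) {
    if (z[j] && z[j - 1]) {
      v <- stats::runif(1, mp$flight_speed_min, mp$flight_speed_max)
      step <- v * dt_s
      if (abs(r + dir * step) > mp$excursion_radius_m) dir <- -sign(r)
      if (dir == 0) dir <- 1
      r <- r + dir * step
    } else if (z[j] && !z[j - 1]) {
      # run start: bird takes off this interval's end; no displacement yet,
      # decide the leg direction (outbound from wherever it sits)
      dir <- if (abs(r) < 1) sign(stats::runif(1, -1, 1)) else sign(r)
      if (dir == 0) dir <- 1
    }
    # mid-run turnaround: head home after half the run
    if (z[j] && z[j - 1]) {
      run_start <- j
      while (run_start > 1 && z[run_start - 1]) run_start <- run_start - 1
      run_end <- j
      while (run_end < n && z[run_end + 1]) run_end <- run_end + 1
      if (j - run_start >= ceiling((run_end - run_start) / 2)) {
        dir <- -sign(r)
        if (dir == 0) dir <- 1
      }
    }
    xs[j] <- r * ux; ys[j] <- r * uy
  }
  cbind(xs, ys)
}

#' Simulate the GPS track of one individual over a date range
#'
#' @param individual one-row data.frame (individual_id, site_id) or a list
#'   with those fields; nest coordinates are looked up in `nests`.
#' @param nests data.frame (site_id, lat, lon).
#' @param experience years on the breeding site (1-15) for these dates.
#' @param dates `Date` vector of days to simulate.
#' @param weather long weather table covering the individual's cell for all
#'   `dates` (a missing day is an error naming the date).
#' @param cells cell grid; the nest's containing cell supplies the daily
#'   weather driving behaviour.
#' @param config a `cpf_sim_config`.
#' @param seed integer seed for this individual's substream.
#' @return list with `fixes` (Movebank-style: individual_id, timestamp, lat,
#'   lon, hdop, n_satellites), and `truth` (`days`: date, p_flight, n_fixes,
#'   k_flight, anchor_violation; `labels`: per-fix rest/perch/flight).
#' @export
simulate_tracks <- function(individual, nests, experience, dates, weather,
                            cells, config, seed) {
  stopifnot(inherits(config, "cpf_sim_config"))
  set.seed(seed)
  id <- individual$individual_id
  site <- individual$site_id
  nest <- nests[nests$site_id == site, ]
  if (nrow(nest) != 1) stop("no nest for site ", site)
  cell <- cell_for_point(cells, nest$lat, nest$lon)
  wx <- weather[weather$cell_id == cell, ]
  wx <- wx[match(as.character(dates), as.character(wx$date)), ]
  if (any(is.na(wx$rain_mm))) {
    stop("missing weather for cell ", cell, " on ",
         format(dates[which(is.na(wx$rain_mm))[1]]))
  }
  bc <- config$behaviour_coefs
  mp <- config$movement_params
  qr_ <- config$qc_violation_rates
  dt_s <- config$fix_interval * 60
  # individual intercept from its own substream: stable across years and
  # unaffected by other individuals
  u <- with_seed(substream_seed(config$seed, 6, id_hash(id)),
                 stats::rnorm(1, 0, bc$individual_sd))
  lp <- bc$intercept + u + bc$rain * wx$rain_mm +
    bc$temp * (wx$temp_c - bc$temp_ref) +
    bc$wind2 * (wx$wind_ms - bc$wind_opt)^2 +
    bc$experience * (experience - bc$exp_ref)
  p_day <- stats::plogis(lp)
  sunrises <- sunrise_utc(nest$lat, nest$lon, dates)

  fixes <- vector("list", length(dates))
  days <- vector("list", length(dates))
  labels <- vector("list", length(dates))
  for (d in seq_along(dates)) {
    n_f <- 1 + stats::rpois(1, max(config$fixes_per_day$mean - 1, 0))
    short <- stats::runif(1) < qr_$short_day
    if (short) n_f <- sample(3:9, 1)
    k <- stats::rbinom(1, n_f - 1, p_day[d])
    if (k == 1) k <- if (stats::runif(1) < 0.5) 2L else 0L
    z <- place_runs(n_f, flight_run_lengths(k))
    anchor_violation <- stats::runif(1) < qr_$anchor
    t0_min <- if (anchor_violation) stats::runif(1, 125, 240) else
      stats::runif(1, -30, 120)
    t_start <- sunrises[d] + t0_min * 60
    # cap the duty cycle before local (UTC+1) midnight so a simulated day
    # never spills into the next civil date
    cutoff <- as.POSIXct(dates[d] + 1, tz = "UTC") - 3600
    n_max <- max(1L, as.integer(floor(as.numeric(cutoff - t_start,
                                                 units = "secs") / dt_s)))
    if (n_f > n_max) {
      n_f <- n_max
      z <- z[seq_len(n_f)]
      # a truncated trailing run of length 1 cannot register as flight
      # under displacement-based classification; demote it
      if (n_f >= 2 && z[n_f] && !z[n_f - 1]) z[n_f] <- FALSE
      if (n_f == 1) z[1] <- FALSE
    }
    pos <- simulate_day_positions(z, dt_s, mp)
    pos <- pos + matrix(stats::rnorm(2 * n_f, 0, mp$gps_noise_sd_m), ncol = 2)
    ll <- unproject_tmerc(pos[, 1], pos[, 2], nest$lat, nest$lon)
    tt <- t_start + (seq_len(n_f) - 1) * dt_s
    hdop <- stats::runif(n_f, 1, 6)
    vh <- stats::runif(n_f) < qr_$hdop
    hdop[vh] <- stats::runif(sum(vh), 10.5, 20)
    nsat <- sample(4:12, n_f, replace = TRUE)
    vs <- stats::runif(n_f) < qr_$satellites & !vh
    nsat[vs] <- sample(0:2, sum(vs), replace = TRUE)
    lab <- ifelse(z, "flight",
                  ifelse(sqrt(pos[, 1]^2 + pos[, 2]^2) < 50, "rest", "perch"))
    fixes[[d]] <- data.frame(
      individual_id = id, timestamp = tt, lat = ll$lat, lon = ll$lon,
      hdop = hdop, n_satellites = nsat, stringsAsFactors = FALSE)
    days[[d]] <- data.frame(
      individual_id = id, date = dates[d], p_flight = p_day[d], u = u,
      n_fixes = n_f, k_flight = sum(z),
      rain_mm = wx$rain_mm[d], temp_c = wx$temp_c[d], wind_ms = wx$wind_ms[d],
      experience = experience,
      short_day = short, anchor_violation = anchor_violation,
      hdop_violations = sum(vh), satellite_violations = sum(vs),
      stringsAsFactors = FALSE)
    labels[[d]] <- lab
  }
  list(fixes = do.call(rbind, fixes),
       truth = list(days = do.call(rbind, days), labels = unlist(labels)))
}
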