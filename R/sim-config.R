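#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' Defaults describe a Mediterranean population of a territorial,
#' central-place-foraging raptor: 15-min GPS duty cycle averaging ~40 fixes
#' per day, a breeding season running from Dec 1 (pre-breeding) through a
#' default Feb 28 laying date, 40 days of incubation and 60 days of rearing,
#' weather from a wet-day Bernoulli x gamma rainfall process, gamma wind and
#' a seasonal temperature sinusoid, and daily flight probability driven on
#' the logit scale by rainfall, temperature, a quadratic wind response with
#' its optimum at 5 m/s, and individual experience.
#'
#' @param n_sites number of breeding sites (default 10).
#' @param n_years number of breeding seasons (default 3).
#' @param first_year first breeding year (default 2019).
#' @param fix_interval minutes between fixes (default 15).
#' @param fixes_per_day list(mean): shifted-Poisson mean fixes/day
#'   (default 40; draw is 1 + Poisson(mean - 1)).
#' @param nest_coords optional data.frame(site_id, lat, lon); generated
#'   around (43.8 N, 4.0 E) when NULL.
#' @param weather_params,behaviour_coefs,movement_params,breeding_coefs,
#'   recruitment_freqs,qc_violation_rates,phase_params named lists merged
#'   over the defaults (see the package vignette for each entry's meaning
#'   and units).
#' @param tracked_fraction fraction of individuals carrying a GPS tag
#'   (default 0.5).
#' @param seed master seed; all generator substreams derive from it by
#'   fixed offsets, so adding an individual does not perturb the others.
#' @return a validated `cpf_sim_config` (a named list).
#' @export
sim_config <- function(n_sites = 10, n_years = 3, first_year = 2019,
                       fix_interval = 15, fixes_per_day = list(),
                       nest_coords = NULL,
                       weather_params = list(), behaviour_coefs = list(),
                       movement_params = list(), breeding_coefs = list(),
                       recruitment_freqs = NULL, qc_violation_rates = list(),
                       phase_params = list(), tracked_fraction = 0.5,
                       seed = 1) {
  merge_defaults <- function(user, def) {
    bad <- setdiff(names(user), names(def))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    def[names(user)] <- user
    def
  }
  cfg <- list(
    n_sites = n_sites, n_years = n_years, first_year = first_year,
    fix_interval = fix_interval,
    fixes_per_day = merge_defaults(fixes_per_day, list(mean = 40)),
    nest_coords = nest_coords,
    weather_params = merge_defaults(weather_params, list(
      wet_p = 0.25,          # wet-day probability
      rain_shape = 0.8,      # gamma shape of wet-day rainfall
      rain_scale = 7.5,      # gamma scale (mm); wet-day mean 6 mm
      wind_mean = 4.5,       # m/s
      wind_shape = 2.5,
      temp_mean = 12,        # deg C annual mean
      temp_amplitude = 8,    # deg C seasonal half-range
      temp_phase_doy = 15,   # coldest day of year
      temp_noise_sd = 2
    )),
    behaviour_coefs = merge_defaults(behaviour_coefs, list(
      intercept = -0.7,      # logit flight probability at the reference point
      rain = -0.30,          # per mm of daily rainfall
      temp = 0.02,           # per deg C away from temp_ref
      wind2 = -0.12,         # curvature of the quadratic wind response
      wind_opt = 5,          # m/s, vertex of the wind response
      experience = -0.05,    # per year on the breeding site beyond exp_ref
      individual_sd = 0.3,   # logit-scale SD of the individual intercept
      temp_ref = 12, exp_ref = 8
    )),
    movement_params = merge_defaults(movement_params, list(
      excursion_radius_m = 7500,
      gps_noise_sd_m = 10,
      flight_speed_min = 3.5,  # m/s; > the 3 m/s threshold so GPS noise
      flight_speed_max = 8     # cannot flip a flight segment below it
    )),
    breeding_coefs = merge_defaults(breeding_coefs, list(
      p_lay = c("0" = 0.95, "F" = 0.71, "M" = 0.85, "MF" = 0.46),
      p_hatch = 0.82, p_fledge = 0.90, p_second_chick = 0.57,
      tmax_slope_hatch = -0.30, tmax_slope_fledge = -0.30,
      male_flight_slope = -0.26
    )),
    recruitment_freqs = if (is.null(recruitment_freqs)) {
      c("0" = 0.70, "F" = 0.12, "M" = 0.12, "MF" = 0.06)
    } else recruitment_freqs,
    qc_violation_rates = merge_defaults(qc_violation_rates, list(
      hdop = 0.01, satellites = 0.005, short_day = 0.01, anchor = 0.02
    )),
    phase_params = merge_defaults(phase_params, list(
      laying_month_day = "02-28", incubation_days = 40, rearing_days = 60
    )),
    tracked_fraction = tracked_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  wp <- cfg$weather_params
  bc <- cfg$breeding_coefs
  probs <- c(wp$wet_p, bc$p_lay, bc$p_hatch, bc$p_fledge, bc$p_second_chick,
             cfg$recruitment_freqs, unlist(cfg$qc_violation_rates),
             cfg$tracked_fraction)
  if (any(probs < 0 | probs > 1)) stop("config: probabilities must lie in [0, 1]")
  scales <- c(wp$rain_shape, wp$rain_scale, wp$wind_mean, wp$wind_shape,
              wp$temp_noise_sd, cfg$movement_params$excursion_radius_m,
              cfg$fixes_per_day$mean, cfg$fix_interval)
  if (any(scales <= 0)) stop("config: scale parameters must be > 0")
  if (abs(sum(cfg$recruitment_freqs) - 1) > 1e-8) {
    stop("config: recruitment_freqs must sum to 1")
  }
  if (!all(names(cfg$recruitment_freqs) %in% c("0", "F", "M", "MF"))) {
    stop("config: recruitment levels must be 0/F/M/MF")
  }
  mp <- cfg$movement_params
  if (mp$flight_speed_min <= 3) stop("config: flight_speed_min must exceed 3 m/s")
  if (mp$flight_speed_max < mp$flight_speed_min) stop("config: flight speed range inverted")
  if (mp$excursion_radius_m < mp$flight_speed_max * cfg$fix_interval * 60) {
    stop("config: excursion_radius_m must be >= flight_speed_max * fix_interval ",
         "(one flight step must fit inside the excursion radius)")
  }
  structure(cfg, class = "cpf_sim_config")
}

# Fixed-offset substream seeds so each stream / individual is reproducible
# independently of the others. Streams: 1 weather, 2 population, 3 tracks
# (indexed per individual), 4 breeding, 5 tagging, 6 individual intercepts.
substream_seed <- function(master, stream, index = 0) {
  as.integer((as.numeric(master) * 7 + stream * 104729 + index * 7919) %% 2147483647)
}

# run expr under a temporary seed, restoring the RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
  })
  expr
}

# stable small integer from an id string
id_hash <- function(id) {
  sum(utf8ToInt(as.character(id)) * seq_len(nchar(as.character(id)))) %% 100000L
}

#' Season phase calendar for a config
#'
#' @param config a `cpf_sim_config`.
#' @param year breeding year.
#' @return data.frame from [phase_windows()].
#' @export
sim_phase_windows <- function(config, year) {
  pp <- config$phase_params
  phase_windows(year,
                laying = as.Date(sprintf("%d-%s", year, pp$laying_month_day)),
                incubation_days = pp$incubation_days,
                rearing_days = pp$rearing_days)
}
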