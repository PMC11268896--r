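#' Simulate a complete synthetic study dataset
#'
#' Orchestrates the four generators into the full set of inputs the analysis
#' pipeline consumes: weather grid, nests/territories, monitored population,
#' GPS tracks for the tagged subset (with planted QC violations and ground
#' truth), and staged breeding outcomes whose covariate effects are the
#' configured ones (max-temperature slopes from the site's own simulated
#' phase weather; the male-rearing-flight link from the latent daily flight
#' probability).
#'
#' @param config a `cpf_sim_config`.
#' @return list: `config`, `cells`, `weather`, `nests`, `individuals`,
#'   `events` (breeding table with outcomes), `fixes` (all tracked birds),
#'   `truth` (per-day latent table + per-fix labels), `windows` (per-year
#'   phase calendar).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "cpf_sim_config"))
  pop <- simulate_population(config)
  if (nrow(pop$nests) == 0) stop("simulate_dataset() needs n_sites >= 1")
  cells <- make_weather_cells(pop$nests$lat, pop$nests$lon)
  years <- config$first_year + seq_len(config$n_years) - 1

  windows <- do.call(rbind, lapply(years, function(y) {
    w <- sim_phase_windows(config, y); w$year <- y; w
  }))
  weather <- do.call(rbind, lapply(seq_along(years), function(i) {
    w <- windows[windows$year == years[i], ]
    start <- min(w$start); end <- max(w$end)
    simulate_weather(start, as.integer(end - start) + 1, cells,
                     config$weather_params,
                     substream_seed(config$seed, 1, i))
  }))

  # tagged subset: deterministic choice given the seed
  set.seed(substream_seed(config$seed, 5))
  ind <- pop$individuals
  n_tracked <- round(nrow(ind) * config$tracked_fraction)
  tracked_ids <- if (n_tracked > 0) sample(ind$individual_id, n_tracked) else character(0)

  site_cell <- stats::setNames(cell_for_point(cells, pop$nests$lat, pop$nests$lon),
                               pop$nests$site_id)
  bc <- config$behaviour_coefs

  # latent mean daily flight probability over a window, from cell weather
  latent_flight <- function(id, site, experience, start, end) {
    wx <- weather[weather$cell_id == site_cell[[site]] &
                    weather$date >= start & weather$date <= end, ]
    u <- with_seed(substream_seed(config$seed, 6, id_hash(id)),
                   stats::rnorm(1, 0, bc$individual_sd))
    lp <- bc$intercept + u + bc$rain * wx$rain_mm +
      bc$temp * (wx$temp_c - bc$temp_ref) +
      bc$wind2 * (wx$wind_ms - bc$wind_opt)^2 +
      bc$experience * (experience - bc$exp_ref)
    mean(stats::plogis(lp))
  }

  ev <- pop$events
  tmax <- function(site, start, end) {
    wx <- weather[weather$cell_id == site_cell[[site]] &
                    weather$date >= start & weather$date <= end, ]
    max(wx$temp_c)
  }
  per_event <- lapply(seq_len(nrow(ev)), function(i) {
    w <- windows[windows$year == ev$year[i], ]
    inc <- w[w$phase == "incubation", ]
    rea <- w[w$phase == "rearing", ]
    c(tmax_inc = tmax(ev$site_id[i], inc$start, inc$end),
      tmax_rea = tmax(ev$site_id[i], rea$start, rea$end),
      male_flight = latent_flight(ev$male_id[i], ev$site_id[i],
                                  ev$male_experience[i],
                                  rea$start, rea$end))
  })
  pe <- do.call(rbind, per_event)
  # degenerate event sets (a single site-year) have no tmax spread
  safe_z <- function(x) if (length(unique(x)) >= 2) standardize(x)$z else
    rep(0, length(x))
  ev$tmax_z_incubation <- safe_z(pe[, "tmax_inc"])
  ev$tmax_z_rearing <- safe_z(pe[, "tmax_rea"])
  events <- simulate_breeding(ev, male_rearing_flight = pe[, "male_flight"],
                              config = config,
                              seed = substream_seed(config$seed, 4))
  events$male_rearing_flight_true <- pe[, "male_flight"]

  # GPS tracks for the tagged subset, one substream per individual-year
  fixes <- list(); truth_days <- list(); truth_labels <- list()
  for (i in seq_len(nrow(ind))) {
    if (!ind$individual_id[i] %in% tracked_ids) next
    sx_col <- if (ind$sex[i] == "M") "male_id" else "female_id"
    ex_col <- if (ind$sex[i] == "M") "male_experience" else "female_experience"
    my_ev <- ev[ev[[sx_col]] == ind$individual_id[i], ]
    for (j in seq_len(nrow(my_ev))) {
      y <- my_ev$year[j]
      w <- windows[windows$year == y, ]
      dates <- seq(min(w$start), max(w$end), by = "day")
      tr <- simulate_tracks(ind[i, ], pop$nests, my_ev[[ex_col]][j], dates,
                            weather, cells, config,
                            substream_seed(config$seed, 3,
                                           i * 100 + (y - config$first_year)))
      fixes[[length(fixes) + 1]] <- tr$fixes
      truth_days[[length(truth_days) + 1]] <- tr$truth$days
      truth_labels[[length(truth_labels) + 1]] <- tr$truth$labels
    }
  }
  ind$tracked <- ind$individual_id %in% tracked_ids

  list(config = config, cells = cells, weather = weather, nests = pop$nests,
       individuals = ind, events = events,
       fixes = if (length(fixes)) do.call(rbind, fixes) else NULL,
       truth = list(days = if (length(truth_days)) do.call(rbind, truth_days) else NULL,
                    labels = unlist(truth_labels)),
       windows = windows)
}

#' Write a simulated dataset to CSV files
#'
#' Emits the external-interface files: `tracks.csv` (Movebank-style columns
#' individual_id, timestamp, location_lat, location_long, hdop,
#' n_satellites), `breeding.csv`, `weather.csv`, `cells.csv`, `nests.csv`,
#' `individuals.csv`, `truth_days.csv` and `config.json`.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (!is.null(dataset$fixes)) {
    tr <- data.frame(
      individual_id = dataset$fixes$individual_id,
      timestamp = strftime(dataset$fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC"),
      location_lat = dataset$fixes$lat,
      location_long = dataset$fixes$lon,
      hdop = dataset$fixes$hdop,
      n_satellites = dataset$fixes$n_satellites)
    utils::write.csv(tr, p("tracks.csv"), row.names = FALSE)
  }
  utils::write.csv(dataset$events, p("breeding.csv"), row.names = FALSE)
  utils::write.csv(dataset$weather, p("weather.csv"), row.names = FALSE)
  utils::write.csv(dataset$cells, p("cells.csv"), row.names = FALSE)
  utils::write.csv(dataset$nests, p("nests.csv"), row.names = FALSE)
  utils::write.csv(dataset$individuals, p("individuals.csv"), row.names = FALSE)
  if (!is.null(dataset$truth$days)) {
    utils::write.csv(dataset$truth$days, p("truth_days.csv"), row.names = FALSE)
  }
  cfg <- dataset$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "nest_coords")],
                       p("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
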