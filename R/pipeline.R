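# End-to-end run orchestration and the command-line surface.

#' Run configuration
#'
#' A flat, typed run configuration: all QC thresholds, the wind-day
#' thresholds, the weather disc area, battery toggles and the seed. Unknown
#' keys are rejected; every threshold is echoed into the run manifest.
#'
#' @param ... overrides of the defaults (see source for the full key list).
#' @return a `cpf_run_config` list.
#' @export
run_config <- function(...) {
  def <- list(
    tracks = NULL, weather = NULL, breeding = NULL, nests = NULL,
    cells = NULL,
    simulate = FALSE, sim_n_sites = 4, sim_n_years = 2,
    tz_offset = 1, hdop_max = 10, min_satellites = 3, min_gap = 15,
    min_fixes = 10, flight_speed = 3, speed_ceiling = 40,
    wind_hi = 7.5, wind_lo = 2.5, disc_area_km2 = 70,
    run_movement_models = TRUE, run_breeding_models = TRUE,
    run_productivity_models = TRUE,
    seed = 1, out_dir = "cpforager_out")
  user <- list(...)
  bad <- setdiff(names(user), names(def))
  if (length(bad)) stop("unknown run-config key(s): ", paste(bad, collapse = ", "))
  def[names(user)] <- user
  structure(def, class = "cpf_run_config")
}

#' Execute the full pipeline
#'
#' Simulate (optional) -> preprocess -> environment joins -> model
#' batteries, writing tidy CSV outputs and a JSON manifest (config echo,
#' package version, seed, and row counts at every filter step) under
#' `config$out_dir`. Any stage error aborts with the stage name.
#'
#' @param config a `cpf_run_config`.
#' @return list of in-memory artifacts (invisibly returns the same objects
#'   written to disk) with the manifest as `$manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cpf_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("cpforager")),
                   config = unclass(config), counts = list())

  if (isTRUE(config$simulate)) {
    sim <- stage("simulate", {
      sc <- sim_config(n_sites = config$sim_n_sites,
                       n_years = config$sim_n_years, seed = config$seed)
      simulate_dataset(sc)
    })
    dir.create(file.path(out_dir, "inputs"), showWarnings = FALSE)
    write_dataset_csv(sim, file.path(out_dir, "inputs"))
    fixes <- sim$fixes
    weather <- sim$weather
    events <- sim$events
    nests <- sim$nests
    cells <- sim$cells
    windows <- sim$windows
    individuals <- sim$individuals
  } else {
    fixes <- stage("read_tracks", read_tracks(config$tracks))
    weather <- stage("read_weather", read_weather(config$weather))
    events <- stage("read_breeding", read_breeding(config$breeding))
    nests <- stage("read_nests", {
      if (is.null(config$nests)) stop("nests CSV required")
      utils::read.csv(config$nests, stringsAsFactors = FALSE)
    })
    cells <- stage("cells", {
      if (!is.null(config$cells)) {
        cc <- utils::read.csv(config$cells, stringsAsFactors = FALSE)
        origin <- c(mean(cc$lat), mean(cc$lon))
        pr <- project_tmerc(cc$lat, cc$lon, origin[1], origin[2])
        cc$cx <- pr$x; cc$cy <- pr$y
        attr(cc, "origin") <- origin
        attr(cc, "size_m") <- 8000
        cc
      } else make_weather_cells(nests$lat, nests$lon)
    })
    windows <- do.call(rbind, lapply(sort(unique(events$year)), function(y) {
      w <- phase_windows(y); w$year <- y; w
    }))
    individuals <- NULL
  }

  metrics <- stage("preprocess", preprocess_tracks(
    fixes, tz_offset = config$tz_offset, min_fixes = config$min_fixes,
    min_gap = config$min_gap, flight_speed = config$flight_speed,
    hdop_max = config$hdop_max, min_satellites = config$min_satellites,
    speed_ceiling = config$speed_ceiling))
  manifest$counts <- attr(metrics, "qc_report")
  utils::write.csv(metrics, file.path(out_dir, "daily_metrics.csv"),
                   row.names = FALSE)

  # phase weather per site-year from the nest disc
  phase_wx <- stage("phase_weather", {
    origin <- attr(cells, "origin")
    rows <- list()
    for (s in seq_len(nrow(nests))) {
      disc <- nest_disc(nests$lat[s], nests$lon[s],
                        area_km2 = config$disc_area_km2, origin = origin)
      for (y in unique(windows$year)) {
        w <- windows[windows$year == y, ]
        for (i in seq_len(nrow(w))) {
          pw <- phase_weather_summary(disc, weather, cells,
                                      w$start[i], w$end[i],
                                      wind_hi = config$wind_hi,
                                      wind_lo = config$wind_lo)
          pw$site_id <- nests$site_id[s]; pw$year <- y; pw$phase <- w$phase[i]
          rows[[length(rows) + 1]] <- pw
        }
      }
    }
    do.call(rbind, rows)
  })
  utils::write.csv(phase_wx, file.path(out_dir, "phase_weather.csv"),
                   row.names = FALSE)

  artifacts <- list(metrics = metrics, phase_weather = phase_wx,
                    manifest = manifest)

  if (isTRUE(config$run_breeding_models)) {
    bm <- stage("breeding_models", fit_breeding_models(events, phase_wx))
    utils::write.csv(bm$coefficients,
                     file.path(out_dir, "breeding_coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(bm$predicted_laying,
                     file.path(out_dir, "predicted_laying.csv"),
                     row.names = FALSE)
    artifacts$breeding_models <- bm
  }

  if (isTRUE(config$run_movement_models) && !is.null(individuals) &&
      !is.null(metrics) && nrow(metrics) > 0) {
    mm <- stage("movement_models", {
      daily <- join_daily_covariates(metrics, individuals, events, nests,
                                     cells, weather, windows)
      fit_movement_models(daily)
    })
    if (!is.null(mm$coefficients)) {
      utils::write.csv(mm$coefficients,
                       file.path(out_dir, "movement_coefficients.csv"),
                       row.names = FALSE)
    }
    artifacts$movement_models <- mm
  }

  manifest$counts_summary <- list(
    n_fixes_in = attr(metrics, "qc_report")$filter_quality$n_in,
    n_metric_days = nrow(metrics))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  artifacts$manifest <- manifest
  invisible(artifacts)
}

#' Join daily metrics to weather, experience and phase
#'
#' Attaches to each admitted individual-day its sex, breeding-site cell
#' weather (rain, temperature, wind), the individual's experience for that
#' year, and the phase label. Days outside all phase windows are dropped.
#'
#' @param metrics daily metrics ([preprocess_tracks()]).
#' @param individuals data.frame (individual_id, sex, site_id).
#' @param events breeding-event table (for per-year experience columns).
#' @param nests,cells,weather environment inputs.
#' @param windows phase calendar with a `year` column.
#' @return joined daily data.frame ready for [fit_movement_models()].
#' @export
join_daily_covariates <- function(metrics, individuals, events, nests,
                                  cells, weather, windows) {
  i <- match(metrics$individual_id, individuals$individual_id)
  metrics$sex <- individuals$sex[i]
  metrics$site_id <- individuals$site_id[i]
  site_cell <- stats::setNames(cell_for_point(cells, nests$lat, nests$lon),
                               nests$site_id)
  metrics$cell_id <- site_cell[metrics$site_id]
  wi <- match(paste(metrics$cell_id, metrics$date),
              paste(weather$cell_id, weather$date))
  metrics$rain <- weather$rain_mm[wi]
  metrics$temp <- weather$temp_c[wi]
  metrics$wind <- weather$wind_ms[wi]
  metrics$phase <- assign_phase(metrics$date, windows)
  # year of the day's season: the window set it fell in
  yr <- rep(NA_integer_, nrow(metrics))
  for (y in unique(windows$year)) {
    w <- windows[windows$year == y, ]
    hit <- metrics$date >= min(w$start) & metrics$date <= max(w$end)
    yr[hit] <- y
  }
  metrics$year <- yr
  ei <- match(paste(metrics$individual_id, metrics$year),
              paste(events$male_id, events$year))
  ei_f <- match(paste(metrics$individual_id, metrics$year),
                paste(events$female_id, events$year))
  ei[is.na(ei)] <- ei_f[is.na(ei)]
  metrics$experience <- ifelse(metrics$sex == "M",
                               events$male_experience[ei],
                               events$female_experience[ei])
  out <- metrics[!is.na(metrics$phase) & !is.na(metrics$rain) &
                   !is.na(metrics$experience), ]
  rownames(out) <- NULL
  out
}
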