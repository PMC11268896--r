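# Weather covariate joins: region-averaged daily weather and phase summaries.

check_weather_columns <- function(weather) {
  need <- c("cell_id", "date", "rain_mm", "temp_c", "wind_ms")
  miss <- setdiff(need, names(weather))
  if (length(miss)) stop("weather table is missing column(s): ",
                         paste(miss, collapse = ", "))
  invisible(weather)
}

#' Daily weather averaged over a region
#'
#' Mean daily rainfall, temperature and wind over the grid cells whose
#' geometry intersects the region (unweighted by default, the literal
#' several-cells-averaged convention; optionally weighted by the overlap
#' fraction).
#'
#' @param region a `cpf_region`.
#' @param weather long weather table (cell_id, date, rain_mm, temp_c,
#'   wind_ms).
#' @param cells cell grid from [make_weather_cells()].
#' @param date a `Date` (vectorised).
#' @param area_weighted weight cells by overlap fraction (default FALSE).
#' @return data.frame (date, rain_mm, temp_c, wind_ms), one row per date.
#' @export
daily_weather_for_region <- function(region, weather, cells, date,
                                     area_weighted = FALSE) {
  check_weather_columns(weather)
  date <- as.Date(date)
  if (area_weighted) {
    w <- region_cells(region, cells, weights = TRUE)
    ids <- names(w)
  } else {
    ids <- region_cells(region, cells)
    w <- stats::setNames(rep(1 / length(ids), length(ids)), ids)
  }
  if (length(ids) == 0) stop("region intersects no weather cell")
  sub <- weather[weather$cell_id %in% ids & as.Date(weather$date) %in% date, ]
  out <- lapply(date, function(d) {
    rows <- sub[as.Date(sub$date) == d, ]
    missing <- setdiff(ids, rows$cell_id)
    if (length(missing)) {
      stop(sprintf("missing weather record(s) for cell %s on %s",
                   paste(missing, collapse = ","), format(d)))
    }
    ww <- w[rows$cell_id]
    ww <- ww / sum(ww)
    data.frame(date = d,
               rain_mm = sum(rows$rain_mm * ww),
               temp_c = sum(rows$temp_c * ww),
               wind_ms = sum(rows$wind_ms * ww))
  })
  do.call(rbind, out)
}

#' Phase-level weather summary
#'
#' Summarizes region-averaged daily weather over a phase window into the
#' covariates the breeding models use: cumulative rainfall; minimum and
#' maximum of the daily mean temperature; and counts of windy
#' (> `wind_hi` m/s) and calm (< `wind_lo` m/s) days, both strict
#' inequalities so a day exactly at a threshold counts in neither bin.
#'
#' @inheritParams daily_weather_for_region
#' @param start,end first and last day of the phase window (inclusive).
#' @param wind_hi,wind_lo wind-day thresholds in m/s (defaults 7.5 and 2.5).
#' @return one-row data.frame: rain_cum_mm, temp_min_c, temp_max_c,
#'   days_wind_above, days_wind_below, n_days.
#' @export
phase_weather_summary <- function(region, weather, cells, start, end,
                                  wind_hi = 7.5, wind_lo = 2.5,
                                  area_weighted = FALSE) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("phase window end precedes start")
  days <- seq(start, end, by = "day")
  daily <- daily_weather_for_region(region, weather, cells, days,
                                    area_weighted = area_weighted)
  data.frame(
    rain_cum_mm = sum(daily$rain_mm),
    temp_min_c = min(daily$temp_c),
    temp_max_c = max(daily$temp_c),
    days_wind_above = sum(daily$wind_ms > wind_hi),
    days_wind_below = sum(daily$wind_ms < wind_lo),
    n_days = length(days)
  )
}

#' Default breeding-phase windows for a season
#'
#' Calendar-default phase windows when laying/hatching dates are unknown:
#' pre-breeding from Dec 1 of the previous year to the (default Feb 28)
#' laying date, incubation the following `incubation_days` days (default
#' 40, the middle of the species' 37-41 d range) and rearing the
#' `rearing_days` after that (default 60, middle of 55-65 d).
#'
#' @param year the breeding year (the one containing laying).
#' @param laying optional laying `Date` (default Feb 28 of `year`).
#' @param hatching optional hatching `Date` (default laying +
#'   `incubation_days`).
#' @param incubation_days,rearing_days phase durations in days.
#' @return data.frame with columns phase, start, end (3 rows).
#' @export
phase_windows <- function(year, laying = NULL, hatching = NULL,
                          incubation_days = 40, rearing_days = 60) {
  if (is.null(laying)) laying <- as.Date(sprintf("%d-02-28", year))
  laying <- as.Date(laying)
  if (is.null(hatching)) hatching <- laying + incubation_days
  hatching <- as.Date(hatching)
  pre_start <- as.Date(sprintf("%d-12-01", year - 1))
  data.frame(
    phase = c("pre-breeding", "incubation", "rearing"),
    start = c(pre_start, laying + 1, hatching + 1),
    end = c(laying, hatching, hatching + rearing_days),
    stringsAsFactors = FALSE
  )
}

#' Phase weather per site-year from single cells
#'
#' Vectorized phase summaries straight from each site's containing cell
#' (no region averaging): for every site, year and phase, cumulative rain,
#' min/max of daily mean temperature and strict-threshold wind-day counts.
#' This is the fast path used when each territory maps to one cell, e.g. on
#' generator output; [phase_weather_summary()] is the general region route.
#'
#' @param weather long weather table.
#' @param site_cell named character vector: site_id -> cell_id.
#' @param windows phase calendar with a `year` column.
#' @inheritParams phase_weather_summary
#' @return data.frame (site_id, year, phase, rain_cum_mm, temp_min_c,
#'   temp_max_c, days_wind_above, days_wind_below, n_days).
#' @export
phase_weather_from_cells <- function(weather, site_cell, windows,
                                     wind_hi = 7.5, wind_lo = 2.5) {
  check_weather_columns(weather)
  wdate <- as.Date(weather$date)
  lab_phase <- rep(NA_character_, nrow(weather))
  lab_year <- rep(NA_integer_, nrow(weather))
  for (i in seq_len(nrow(windows))) {
    hit <- wdate >= windows$start[i] & wdate <= windows$end[i]
    lab_phase[hit] <- windows$phase[i]
    lab_year[hit] <- windows$year[i]
  }
  ok <- !is.na(lab_phase)
  w <- weather[ok, ]
  key <- paste(w$cell_id, lab_year[ok], lab_phase[ok], sep = "\r")
  agg <- function(v, f) tapply(v, key, f)
  cell_tab <- data.frame(
    key = names(agg(w$rain_mm, sum)),
    rain_cum_mm = as.numeric(agg(w$rain_mm, sum)),
    temp_min_c = as.numeric(agg(w$temp_c, min)),
    temp_max_c = as.numeric(agg(w$temp_c, max)),
    days_wind_above = as.numeric(agg(w$wind_ms, function(x) sum(x > wind_hi))),
    days_wind_below = as.numeric(agg(w$wind_ms, function(x) sum(x < wind_lo))),
    n_days = as.numeric(agg(w$wind_ms, length)),
    stringsAsFactors = FALSE)
  grid <- expand.grid(site_id = names(site_cell),
                      year = unique(windows$year),
                      phase = unique(windows$phase),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$key <- paste(site_cell[grid$site_id], grid$year, grid$phase, sep = "\r")
  i <- match(grid$key, cell_tab$key)
  out <- cbind(grid[c("site_id", "year", "phase")],
               cell_tab[i, setdiff(names(cell_tab), "key")])
  rownames(out) <- NULL
  out[!is.na(out$rain_cum_mm), ]
}

#' Assign breeding phases to dates
#'
#' @param date `Date` vector.
#' @param windows data.frame from [phase_windows()].
#' @return character vector of phase labels (`NA` outside all windows).
#' @export
assign_phase <- function(date, windows) {
  date <- as.Date(date)
  out <- rep(NA_character_, length(date))
  for (i in seq_len(nrow(windows))) {
    hit <- date >= windows$start[i] & date <= windows$end[i]
    out[hit] <- windows$phase[i]
  }
  out
}
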