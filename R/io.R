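# Readers and writers for the external CSV interfaces.

#' Read a Movebank-style tracking CSV
#'
#' Expects columns individual_id, timestamp (ISO-8601 UTC), location_lat,
#' location_long and optionally hdop, n_satellites. Timestamps are parsed to
#' POSIXct UTC (an unparseable one is an error naming the row); rows are
#' sorted by (individual, time) so input order never matters.
#'
#' @param path CSV file path.
#' @return fix data.frame (individual_id, timestamp, lat, lon, hdop,
#'   n_satellites).
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("tracking file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "timestamp", "location_lat", "location_long")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("tracking CSV is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("tracking CSV has a header but no rows")
    return(data.frame(individual_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      lat = numeric(), lon = numeric(),
                      hdop = numeric(), n_satellites = integer(),
                      stringsAsFactors = FALSE))
  }
  ts <- as.POSIXct(strptime(raw$timestamp, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  bad <- is.na(ts)
  if (any(bad)) {
    ts[bad] <- as.POSIXct(strptime(raw$timestamp[bad], "%Y-%m-%d %H:%M:%OS",
                                   tz = "UTC"))
  }
  if (any(is.na(ts))) {
    stop("unparseable timestamp at row ", which(is.na(ts))[1], ": ",
         raw$timestamp[which(is.na(ts))[1]])
  }
  out <- data.frame(
    individual_id = as.character(raw$individual_id),
    timestamp = ts,
    lat = as.numeric(raw$location_lat),
    lon = as.numeric(raw$location_long),
    hdop = if ("hdop" %in% names(raw)) as.numeric(raw$hdop) else NA_real_,
    n_satellites = if ("n_satellites" %in% names(raw))
      as.integer(raw$n_satellites) else NA_integer_,
    stringsAsFactors = FALSE)
  out <- out[order(out$individual_id, out$timestamp), ]
  rownames(out) <- NULL
  out
}

#' Read a long-format daily weather CSV
#' @param path CSV with columns cell_id, date, rain_mm, temp_c, wind_ms.
#' @return weather data.frame with `date` as `Date`.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop("weather file not found: ", path)
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_weather_columns(w)
  w$date <- as.Date(w$date)
  if (anyNA(w$date)) stop("unparseable date in weather CSV")
  if (any(w$rain_mm < 0 | w$wind_ms < 0, na.rm = TRUE)) {
    stop("weather CSV has negative rain or wind")
  }
  if (anyDuplicated(w[c("cell_id", "date")])) {
    stop("weather CSV has duplicate (cell, date) records")
  }
  w
}

#' Read a breeding-event CSV
#' @param path CSV with site_id, year, recruitment, laid, hatched, fledged,
#'   n_fledged (+ optional ids/dates).
#' @return validated breeding-event data.frame.
#' @export
read_breeding <- function(path) {
  if (!file.exists(path)) stop("breeding file not found: ", path)
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(recruitment = "character"))
  for (col in c("laid", "hatched", "fledged")) {
    if (col %in% names(ev)) ev[[col]] <- as.logical(ev[[col]])
  }
  validate_breeding_events(ev)
  ev
}
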