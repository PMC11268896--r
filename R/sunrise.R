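#' Apparent sunrise and sunset times (UTC)
#'
#' Computes the UTC instants of apparent sunrise and sunset (solar zenith
#' 90.833 degrees, accounting for standard refraction and the solar disc
#' radius) using the NOAA low-order Fourier-series solar-position
#' equations. Accuracy is within a couple of minutes at mid latitudes,
#' which is ample for a +/- 30/120 min anchoring window.
#'
#' @param lat,lon position in decimal degrees (WGS84). `abs(lat)` must be
#'   below the polar circle; polar day/night raises an error.
#' @param date a `Date` (or something coercible via [as.Date()]).
#' @return a `POSIXct` UTC instant (vectorised over inputs).
#' @export
#' @examples
#' sunrise_utc(43.6, 3.9, as.Date("2020-06-21"))
sunrise_utc <- function(lat, lon, date) {
  solar_event_utc(lat, lon, date, rise = TRUE)
}

#' @rdname sunrise_utc
#' @export
sunset_utc <- function(lat, lon, date) {
  solar_event_utc(lat, lon, date, rise = FALSE)
}

solar_event_utc <- function(lat, lon, date, rise) {
  date <- as.Date(date)
  n <- max(length(lat), length(lon), length(date))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n); date <- rep_len(date, n)
  if (any(abs(lat) >= 66.5)) {
    stop("sunrise_utc() supports |lat| < 66.5 degrees only (no polar day/night)")
  }
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  # fractional year at solar noon, radians
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  p <- pi / 180
  cos_ha <- cos(90.833 * p) / (cos(lat * p) * cos(decl)) - tan(lat * p) * tan(decl)
  if (any(cos_ha < -1 | cos_ha > 1)) {
    bad <- which(cos_ha < -1 | cos_ha > 1)[1]
    stop(sprintf("no sunrise/sunset at lat %.2f on %s (polar day or night)",
                 lat[bad], format(date[bad])))
  }
  ha <- acos(cos_ha) / p                       # degrees
  if (!rise) ha <- -ha
  minutes <- 720 - 4 * (lon + ha) - eqtime     # minutes after 00:00 UTC
  as.POSIXct(date, tz = "UTC") + minutes * 60
}
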