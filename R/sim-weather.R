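#' Simulate a daily gridded weather surface
#'
#' One record per cell per day: rainfall is a wet-day Bernoulli times a
#' gamma amount; wind is gamma with the configured mean and shape;
#' temperature follows the seasonal sinusoid (coldest at `temp_phase_doy`)
#' plus Gaussian noise. Cells are independent given the day; the sinusoid is
#' shared. Identical seed gives identical output.
#'
#' @param start first day (`Date`).
#' @param n_days number of days (>= 1).
#' @param cells cell grid ([make_weather_cells()]) or any data.frame with a
#'   `cell_id` column.
#' @param params `weather_params` list (see [sim_config()]).
#' @param seed integer seed.
#' @return long data.frame (cell_id, date, rain_mm, temp_c, wind_ms).
#' @export
simulate_weather <- function(start, n_days, cells, params, seed) {
  if (n_days < 1) stop("n_days must be >= 1")
  if (any(c(params$rain_shape, params$rain_scale, params$wind_mean,
            params$wind_shape) <= 0) ||
      params$wet_p < 0 || params$wet_p > 1) {
    stop("invalid weather params")
  }
  set.seed(seed)
  dates <- as.Date(start) + seq_len(n_days) - 1
  grid <- expand.grid(cell_id = cells$cell_id, date = dates,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- nrow(grid)
  doy <- as.integer(strftime(grid$date, "%j", tz = "UTC"))
  seasonal <- params$temp_mean -
    params$temp_amplitude * cos(2 * pi * (doy - params$temp_phase_doy) / 365.25)
  wet <- stats::rbinom(m, 1, params$wet_p)
  rain <- wet * stats::rgamma(m, shape = params$rain_shape,
                              scale = params$rain_scale)
  wind <- stats::rgamma(m, shape = params$wind_shape,
                        scale = params$wind_mean / params$wind_shape)
  temp <- seasonal + stats::rnorm(m, 0, params$temp_noise_sd)
  data.frame(cell_id = grid$cell_id, date = grid$date,
             rain_mm = rain, temp_c = temp, wind_ms = wind,
             stringsAsFactors = FALSE)
}
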