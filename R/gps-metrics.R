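# Daily segmentation and the three daily movement metrics.

#' Segment cleaned fixes into individual-days
#'
#' Groups fixes by local civil date (a fixed UTC offset, study-region
#' default +1), drops days with fewer than `min_fixes` locations, computes
#' sunrise at the day's first fix and flags whether that first fix falls in
#' the morning anchoring window `[sunrise - 30 min, sunrise + 120 min]`.
#'
#' @param fixes cleaned, thinned fix data.frame.
#' @param tz_offset hours added to UTC to obtain the local civil date
#'   (default 1).
#' @param min_fixes minimum locations per admitted day (default 10).
#' @param window_before,window_after anchoring window half-widths in minutes
#'   (defaults 30 before and 120 after sunrise).
#' @return list of `cpf_track` objects (individual_id, date, fixes, sunrise,
#'   anchor_ok, n_fixes), with attr `"qc"` counting dropped short days.
#' @export
build_daily_tracks <- function(fixes, tz_offset = 1, min_fixes = 10,
                               window_before = 30, window_after = 120) {
  check_fix_columns(fixes)
  if (nrow(fixes) == 0) {
    out <- list()
    attr(out, "qc") <- qc_counts(n_days_in = 0L, dropped_short_days = 0L,
                                 n_days_out = 0L)
    return(out)
  }
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), , drop = FALSE]
  local_date <- as.Date(fixes$timestamp + tz_offset * 3600, tz = "UTC")
  key <- paste(fixes$individual_id, local_date, sep = "\r")
  idx_by_day <- split(seq_len(nrow(fixes)), key)
  n_days_in <- length(idx_by_day)
  keep <- vapply(idx_by_day, length, 1L) >= min_fixes
  dropped <- sum(!keep)
  idx_by_day <- idx_by_day[keep]

  tracks <- lapply(idx_by_day, function(idx) {
    day_fixes <- fixes[idx, , drop = FALSE]
    rownames(day_fixes) <- NULL
    date <- as.Date(day_fixes$timestamp[1] + tz_offset * 3600, tz = "UTC")
    sr <- sunrise_utc(day_fixes$lat[1], day_fixes$lon[1], date)
    dt_min <- as.numeric(difftime(day_fixes$timestamp[1], sr, units = "mins"))
    structure(list(
      individual_id = day_fixes$individual_id[1],
      date = date,
      fixes = day_fixes,
      sunrise = sr,
      anchor_ok = dt_min >= -window_before & dt_min <= window_after,
      n_fixes = nrow(day_fixes)
    ), class = "cpf_track")
  })
  names(tracks) <- NULL
  attr(tracks, "qc") <- qc_counts(n_days_in = n_days_in,
                                  dropped_short_days = dropped,
                                  n_days_out = length(tracks))
  tracks
}

#' Per-fix speeds from consecutive displacements
#'
#' Segment speed is great-circle distance over elapsed time for each
#' consecutive fix pair; a fix's speed is then the maximum of its adjacent
#' segment speeds (endpoints take their single segment), so that a fix
#' bounding a moving segment counts as moving. Alternatives: `"mean"` of the
#' adjacent segments, or `"forward"` (each fix takes its outgoing segment,
#' the last fix its incoming one).
#'
#' @param track a `cpf_track` with at least 2 fixes.
#' @param method one of "max" (default), "mean", "forward".
#' @return numeric vector of speeds (m/s), one per fix.
#' @export
segment_speeds <- function(track, method = c("max", "mean", "forward")) {
  method <- match.arg(method)
  f <- track$fixes
  n <- nrow(f)
  if (n < 2) stop("segment_speeds() needs >= 2 fixes")
  d <- haversine_m(f$lat[-n], f$lon[-n], f$lat[-1], f$lon[-1])
  dt <- diff(as.numeric(f$timestamp))
  if (any(dt <= 0)) stop("zero or negative elapsed time between fixes")
  seg <- d / dt
  switch(method,
         max = pmax(c(seg[1], seg), c(seg, seg[n - 1])),
         mean = (c(seg[1], seg) + c(seg, seg[n - 1])) / 2,
         forward = c(seg, seg[n - 1]))
}

#' Daily range of movement
#'
#' Median great-circle distance from each location of the day to the day's
#' first (anchor) location, the anchor itself excluded from the median set.
#' Defined only when the first fix lies in the morning anchoring window;
#' otherwise `NA` (absent, not zero).
#'
#' @param track a `cpf_track`.
#' @return metres, or `NA_real_` when the anchor rule fails.
#' @export
daily_range <- function(track) {
  if (!isTRUE(track$anchor_ok)) return(NA_real_)
  f <- track$fixes
  d <- haversine_m(f$lat[1], f$lon[1], f$lat[-1], f$lon[-1])
  stats::median(d)
}

#' Trajectory straightness D/L
#'
#' Net great-circle displacement between the day's first and last fixes (D)
#' divided by the great-circle path length through all fixes (L), clamped to
#' \[0, 1\]. A fully stationary day (L = 0) has no defined straightness and
#' returns `NA`.
#'
#' @param track a `cpf_track` with at least 2 fixes.
#' @return dimensionless value in \[0, 1\], or `NA_real_` when L = 0.
#' @export
straightness <- function(track) {
  f <- track$fixes
  n <- nrow(f)
  if (n < 2) stop("straightness() needs >= 2 fixes")
  D <- haversine_m(f$lat[1], f$lon[1], f$lat[n], f$lon[n])
  L <- sum(haversine_m(f$lat[-n], f$lon[-n], f$lat[-1], f$lon[-1]))
  if (L <= 0) return(NA_real_)
  min(1, max(0, D / L))
}

#' Assemble the three daily metrics for one admitted day
#'
#' @param track a `cpf_track`.
#' @param flight_speed flight classification threshold in m/s (default 3;
#'   strict `>`).
#' @param speed_method passed to [segment_speeds()].
#' @param daylight_only restrict fixes to `[sunrise - 30 min, sunset +
#'   30 min]` before computing metrics (default FALSE; solar-powered tags
#'   rarely record at night, so this usually changes nothing).
#' @return one-row data.frame: individual_id, date, n_fixes, k_flight,
#'   prop_flight, range_m, straightness, anchor_ok.
#' @export
compute_daily_metrics <- function(track, flight_speed = 3,
                                  speed_method = "max",
                                  daylight_only = FALSE) {
  if (daylight_only) {
    f <- track$fixes
    ss <- sunset_utc(f$lat[1], f$lon[1], track$date)
    keep <- f$timestamp >= track$sunrise - 30 * 60 &
      f$timestamp <= ss + 30 * 60
    if (sum(keep) < 2) {
      return(data.frame(individual_id = track$individual_id,
                        date = track$date, n_fixes = sum(keep),
                        k_flight = NA_integer_, prop_flight = NA_real_,
                        range_m = NA_real_, straightness = NA_real_,
                        anchor_ok = track$anchor_ok,
                        stringsAsFactors = FALSE))
    }
    track$fixes <- f[keep, , drop = FALSE]
    track$n_fixes <- sum(keep)
  }
  sp <- segment_speeds(track, method = speed_method)
  k <- sum(sp > flight_speed)
  data.frame(
    individual_id = track$individual_id,
    date = track$date,
    n_fixes = track$n_fixes,
    k_flight = k,
    prop_flight = k / track$n_fixes,
    range_m = daily_range(track),
    straightness = straightness(track),
    anchor_ok = track$anchor_ok,
    stringsAsFactors = FALSE
  )
}

#' Full preprocessing pipeline: raw fixes to daily metrics
#'
#' Runs quality filtering, minimum-interval thinning, daily segmentation and
#' metric computation in one call. The result carries a structured QC report
#' (attr `"qc_report"`) with counts in/out at every rule, for the run
#' manifest.
#'
#' @inheritParams filter_quality
#' @inheritParams thin_min_interval
#' @inheritParams build_daily_tracks
#' @inheritParams compute_daily_metrics
#' @param anchor_global if TRUE, days failing the sunrise-anchor rule are
#'   dropped from ALL metrics, not only from the range (default FALSE: the
#'   anchor rule belongs to the range metric's definition).
#' @return data.frame of daily metrics, one row per admitted individual-day.
#' @export
preprocess_tracks <- function(fixes, tz_offset = 1, min_fixes = 10,
                              min_gap = 15, flight_speed = 3,
                              hdop_max = 10, min_satellites = 3,
                              speed_ceiling = 40, speed_method = "max",
                              anchor_global = FALSE, daylight_only = FALSE) {
  f1 <- filter_quality(fixes, hdop_max = hdop_max,
                       min_satellites = min_satellites,
                       speed_ceiling = speed_ceiling)
  qc1 <- attr(f1, "qc")
  f2 <- thin_min_interval(f1, min_gap = min_gap)
  qc2 <- attr(f2, "qc")
  tracks <- build_daily_tracks(f2, tz_offset = tz_offset, min_fixes = min_fixes)
  qc3 <- attr(tracks, "qc")
  if (anchor_global) {
    n_before <- length(tracks)
    tracks <- Filter(function(t) isTRUE(t$anchor_ok), tracks)
    qc3$dropped_anchor_days <- n_before - length(tracks)
  }
  metrics <- do.call(rbind, lapply(tracks, compute_daily_metrics,
                                   flight_speed = flight_speed,
                                   speed_method = speed_method,
                                   daylight_only = daylight_only))
  if (is.null(metrics)) {
    metrics <- data.frame(individual_id = character(), date = as.Date(character()),
                          n_fixes = integer(), k_flight = integer(),
                          prop_flight = numeric(), range_m = numeric(),
                          straightness = numeric(), anchor_ok = logical(),
                          stringsAsFactors = FALSE)
  }
  rownames(metrics) <- NULL
  attr(metrics, "qc_report") <- list(filter_quality = qc1,
                                     thin_min_interval = qc2,
                                     daily_tracks = qc3)
  metrics
}
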