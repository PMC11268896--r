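# Quality control of raw GPS fixes.
#
# A fix table is a data.frame with columns individual_id, timestamp (POSIXct
# UTC), lat, lon and optionally hdop and n_satellites. QC counts are carried
# on the result as attr(, "qc") so the run manifest can report exact removal
# counts per rule.

qc_counts <- function(...) {
  out <- list(...)
  structure(out, class = "cpf_qc")
}

check_fix_columns <- function(fixes) {
  need <- c("individual_id", "timestamp", "lat", "lon")
  miss <- setdiff(need, names(fixes))
  if (length(miss)) stop("fix table is missing column(s): ", paste(miss, collapse = ", "))
  if (!inherits(fixes$timestamp, "POSIXct")) stop("timestamp must be POSIXct (UTC)")
  if (any(fixes$lat < -90 | fixes$lat > 90, na.rm = TRUE)) stop("lat outside [-90, 90]")
  if (any(fixes$lon < -180 | fixes$lon > 180, na.rm = TRUE)) stop("lon outside [-180, 180]")
  invisible(fixes)
}

#' Quality-filter GPS fixes
#'
#' Applies the standard biologging QC rules: drop fixes with horizontal
#' dilution of precision (Hdop) strictly above `hdop_max`, or strictly fewer
#' than `min_satellites` satellites (fixes with missing quality metadata are
#' retained and counted, since some tag brands do not report these fields);
#' drop exact duplicate timestamps within an individual (first kept); then
#' drop fixes whose implied speed from the previous retained fix exceeds
#' `speed_ceiling` (the later fix of the pair is removed). Input order does
#' not matter: rows are sorted by (individual, time) internally.
#'
#' @param fixes fix data.frame (individual_id, timestamp, lat, lon, and
#'   optionally hdop, n_satellites).
#' @param hdop_max Hdop ceiling (default 10; strict inequality).
#' @param min_satellites minimum satellite count (default 3; strict `<`
#'   removal).
#' @param speed_ceiling implied-speed outlier ceiling in m/s (default 40).
#' @return filtered fix data.frame with an attr `"qc"` holding removal
#'   counts per rule.
#' @export
filter_quality <- function(fixes, hdop_max = 10, min_satellites = 3,
                           speed_ceiling = 40) {
  check_fix_columns(fixes)
  n_in <- nrow(fixes)
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), , drop = FALSE]

  hdop <- if ("hdop" %in% names(fixes)) fixes$hdop else rep(NA_real_, nrow(fixes))
  nsat <- if ("n_satellites" %in% names(fixes)) fixes$n_satellites else rep(NA_real_, nrow(fixes))
  missing_hdop <- sum(is.na(hdop))
  missing_sat <- sum(is.na(nsat))
  bad_hdop <- !is.na(hdop) & hdop > hdop_max
  bad_sat <- !is.na(nsat) & nsat < min_satellites
  removed_hdop <- sum(bad_hdop)
  removed_sat <- sum(bad_sat & !bad_hdop)   # attribute each removal to one rule
  fixes <- fixes[!(bad_hdop | bad_sat), , drop = FALSE]

  dup <- duplicated(fixes[c("individual_id", "timestamp")])
  removed_dup <- sum(dup)
  fixes <- fixes[!dup, , drop = FALSE]

  # greedy implied-speed scan per individual: drop the later fix of any pair
  # faster than the ceiling, then continue from the last kept fix
  keep <- rep(TRUE, nrow(fixes))
  if (nrow(fixes) >= 2 && is.finite(speed_ceiling)) {
    for (idx in split(seq_len(nrow(fixes)), fixes$individual_id)) {
      if (length(idx) < 2) next
      last <- idx[1]
      for (i in idx[-1]) {
        dt <- as.numeric(difftime(fixes$timestamp[i], fixes$timestamp[last],
                                  units = "secs"))
        d <- haversine_m(fixes$lat[last], fixes$lon[last],
                         fixes$lat[i], fixes$lon[i])
        if (dt > 0 && d / dt > speed_ceiling) keep[i] <- FALSE else last <- i
      }
    }
  }
  removed_speed <- sum(!keep)
  fixes <- fixes[keep, , drop = FALSE]
  rownames(fixes) <- NULL
  attr(fixes, "qc") <- qc_counts(
    n_in = n_in, removed_hdop = removed_hdop, removed_satellites = removed_sat,
    removed_duplicate = removed_dup, removed_speed = removed_speed,
    missing_hdop = missing_hdop, missing_satellites = missing_sat,
    n_out = nrow(fixes))
  fixes
}

#' Thin fixes to a minimum time interval
#'
#' Greedy thinning: the first fix of each individual is kept, and each
#' subsequent fix is kept iff its gap to the last *kept* fix is at least
#' `min_gap` minutes (boundary inclusive).
#'
#' @param fixes fix data.frame, time-ordered within individual.
#' @param min_gap minimum gap in minutes (default 15).
#' @return thinned fix data.frame with attr `"qc"` (n_in, removed_thinning,
#'   n_out).
#' @export
thin_min_interval <- function(fixes, min_gap = 15) {
  check_fix_columns(fixes)
  n_in <- nrow(fixes)
  keep <- rep(TRUE, nrow(fixes))
  gap_s <- min_gap * 60
  for (idx in split(seq_len(nrow(fixes)), fixes$individual_id)) {
    tt <- as.numeric(fixes$timestamp[idx])
    if (is.unsorted(tt)) {
      stop("thin_min_interval(): fixes not time-ordered for individual ",
           fixes$individual_id[idx[1]])
    }
    if (length(idx) < 2) next
    last_t <- tt[1]
    for (j in 2:length(idx)) {
      if (tt[j] - last_t >= gap_s) last_t <- tt[j] else keep[idx[j]] <- FALSE
    }
  }
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- qc_counts(n_in = n_in, removed_thinning = sum(!keep),
                               n_out = nrow(out))
  out
}
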