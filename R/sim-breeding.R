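#' Simulate staged breeding outcomes
#'
#' Laying is Bernoulli with a probability per recruitment level; hatching
#' (given laying) and fledging (given hatching) are Bernoulli on the logit
#' scale with the configured maximum-temperature slopes; the fledgling count
#' is 0 unless the pair fledged, else 1 plus a second-chick Bernoulli. The
#' configured male-rearing-flight slope enters the second-chick probability
#' as `p2(z) = clamp(p2 + slope / P(fledged) * z, 0, 1)` with `z` the
#' standardized flight summary, so the implied population-level linear slope
#' of the expected count on `z` equals the configured value (up to clamping,
#' see the vignette).
#'
#' @param events data.frame with a `recruitment` column (levels 0/F/M/MF)
#'   and optional standardized max-temperature columns `tmax_z_incubation`
#'   and `tmax_z_rearing` (default 0).
#' @param male_rearing_flight optional per-event numeric summary (e.g. the
#'   male's mean rearing-phase flight proportion); standardized internally.
#'   When NULL the term is dropped.
#' @param config a `cpf_sim_config`.
#' @param seed integer seed.
#' @return `events` with columns laid, hatched, fledged (logical; staged
#'   outcomes are NA when their parent stage failed) and n_fledged (0/1/2).
#' @export
simulate_breeding <- function(events, male_rearing_flight = NULL, config,
                              seed) {
  stopifnot(inherits(config, "cpf_sim_config"))
  bc <- config$breeding_coefs
  n <- nrow(events)
  lv <- events$recruitment
  unknown <- setdiff(unique(lv), names(bc$p_lay))
  if (length(unknown)) stop("unknown recruitment level(s): ",
                            paste(unknown, collapse = ", "))
  set.seed(seed)
  tz_inc <- if ("tmax_z_incubation" %in% names(events)) events$tmax_z_incubation else rep(0, n)
  tz_rea <- if ("tmax_z_rearing" %in% names(events)) events$tmax_z_rearing else rep(0, n)

  z <- rep(0, n); t_cal <- 0
  if (!is.null(male_rearing_flight) &&
      length(unique(male_rearing_flight)) < 2) {
    male_rearing_flight <- NULL   # a single event carries no flight contrast
  }
  if (!is.null(male_rearing_flight)) {
    z <- standardize(male_rearing_flight)$z
    t_cal <- calibrate_flight_slope(bc$male_flight_slope, bc$p_second_chick,
                                    bc$p_fledge, mean(bc$p_lay[lv]) * bc$p_hatch)
  }

  laid <- stats::rbinom(n, 1, bc$p_lay[lv]) == 1
  p_h <- stats::plogis(stats::qlogis(bc$p_hatch) + bc$tmax_slope_hatch * tz_inc)
  hatched <- ifelse(laid, stats::rbinom(n, 1, p_h) == 1, NA)
  p_f <- stats::plogis(stats::qlogis(bc$p_fledge) + bc$tmax_slope_fledge * tz_rea +
                         t_cal * z)
  fledged <- ifelse(laid & !is.na(hatched) & hatched,
                    stats::rbinom(n, 1, p_f) == 1, NA)
  fledged[!is.na(hatched) & !hatched] <- NA

  p2 <- pmin(1, pmax(0, bc$p_second_chick + t_cal * z))
  second <- stats::rbinom(n, 1, p2)
  n_fledged <- ifelse(!is.na(fledged) & fledged, 1 + second, 0)

  out <- events
  out$laid <- laid
  out$hatched <- hatched
  out$fledged <- fledged
  out$n_fledged <- as.integer(n_fledged)
  out
}

# The flight covariate z enters the fledging stage on the logit scale and
# the second-chick probability linearly (clamped), both through one dial t.
# Calibrate t by root finding so the implied population least-squares slope
# of E[count] on z ~ N(0,1) equals the configured target exactly:
#   E[count | z] = P(laid) P(hatch) plogis(qlogis(p_f) + t z) (1 + p2(z)).
calibrate_flight_slope <- function(target, p2_0, p_fledge, p_lh_marg) {
  if (target == 0) return(0)
  zg <- seq(-6, 6, length.out = 2001)
  wz <- stats::dnorm(zg); wz <- wz / sum(wz)
  implied <- function(t) {
    qz <- stats::plogis(stats::qlogis(p_fledge) + t * zg)
    p2z <- pmin(1, pmax(0, p2_0 + t * zg))
    sum(wz * p_lh_marg * qz * (1 + p2z) * zg) / sum(wz * zg^2)
  }
  lim <- implied(sign(target) * 20)   # saturation bound of the mechanism
  if (abs(target) >= abs(lim)) {
    warning("configured flight slope ", target,
            " exceeds the attainable magnitude ", round(lim, 3),
            "; using the saturating value")
    return(sign(target) * 20)
  }
  stats::uniroot(function(t) implied(t) - target,
                 interval = sort(c(0, sign(target) * 20)),
                 tol = 1e-10)$root
}

#' Validate the staging invariants of a breeding-event table
#'
#' Checks: hatched implies laid; fledged implies hatched; `n_fledged > 0`
#' iff fledged; `n_fledged <= 2`; recruitment levels in 0/F/M/MF. Staged
#' outcomes may be NA only when the parent stage failed.
#'
#' @param events breeding-event data.frame.
#' @return `events`, invisibly; errors on violation.
#' @export
validate_breeding_events <- function(events) {
  need <- c("recruitment", "laid", "n_fledged")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(events$recruitment %in% c("0", "F", "M", "MF"))) {
    stop("recruitment levels must be 0/F/M/MF")
  }
  hatched <- if ("hatched" %in% names(events)) events$hatched else NULL
  fledged <- if ("fledged" %in% names(events)) events$fledged else NULL
  if (!is.null(hatched) && any(!is.na(hatched) & hatched & !events$laid)) {
    stop("staging violation: hatched without laid")
  }
  if (!is.null(fledged) && !is.null(hatched) &&
      any(!is.na(fledged) & fledged & (is.na(hatched) | !hatched))) {
    stop("staging violation: fledged without hatched")
  }
  if (any(events$n_fledged < 0 | events$n_fledged > 2)) {
    stop("n_fledged must be in {0, 1, 2}")
  }
  if (!is.null(fledged)) {
    pos <- events$n_fledged > 0
    fl <- !is.na(fledged) & fledged
    if (any(pos != fl)) stop("staging violation: n_fledged > 0 must match fledged")
  }
  invisible(events)
}
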