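# The concrete model battery: breeding-stage GLMMs, per-sex x per-phase
# movement models, phase/sex comparison, descriptive (CV%) tables, and the
# movement -> productivity link.

#' Assign phases to daily metrics and average per individual x phase
#'
#' @param metrics daily-metrics data.frame (from [preprocess_tracks()])
#'   with an added `sex` column.
#' @param windows phase calendar with columns phase, start, end (and
#'   optionally year; all years' windows are applied).
#' @return data.frame of phase means: individual_id, sex, phase,
#'   prop_flight, range_m, straightness, n_days.
#' @export
phase_means <- function(metrics, windows) {
  metrics$phase <- assign_phase(metrics$date, windows)
  m <- metrics[!is.na(metrics$phase), ]
  if (nrow(m) == 0) stop("no metric days fall inside the phase windows")
  key <- interaction(m$individual_id, m$phase, drop = TRUE)
  agg <- lapply(split(m, key), function(d) {
    data.frame(individual_id = d$individual_id[1],
               sex = if ("sex" %in% names(d)) d$sex[1] else NA_character_,
               phase = d$phase[1],
               prop_flight = mean(d$prop_flight),
               range_m = mean(d$range_m, na.rm = TRUE),
               straightness = mean(d$straightness, na.rm = TRUE),
               n_days = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Descriptive table of phase-averaged movement behaviours
#'
#' Per sex and period (all periods plus each phase) and per metric: mean,
#' SD, min, max and the coefficient of variation CV% = 100 * SD / mean
#' across individuals (sample SD; CV is `NA` when the mean is 0). The
#' "all periods" row averages each individual's phase means first.
#'
#' @param pm phase means from [phase_means()].
#' @return long data.frame: sex, period, metric, mean, sd, min, max, cv_pct.
#' @export
descriptive_table <- function(pm) {
  metrics <- c("prop_flight", "range_m", "straightness")
  rows <- list()
  for (sx in unique(pm$sex)) {
    d <- pm[pm$sex == sx, ]
    all_ind <- lapply(split(d, d$individual_id), function(x) {
      vapply(metrics, function(mm) mean(x[[mm]], na.rm = TRUE), 1)
    })
    all_mat <- do.call(rbind, all_ind)
    for (period in c("all", "pre-breeding", "incubation", "rearing")) {
      vals <- if (period == "all") all_mat else {
        dd <- d[d$phase == period, ]
        as.matrix(dd[metrics])
      }
      if (is.null(dim(vals)) || nrow(vals) == 0) next
      for (mm in metrics) {
        v <- vals[, mm]; v <- v[is.finite(v)]
        if (!length(v)) next
        mu <- mean(v); sdv <- stats::sd(v)
        rows[[length(rows) + 1]] <- data.frame(
          sex = sx, period = period, metric = mm,
          mean = mu, sd = sdv, min = min(v), max = max(v),
          cv_pct = if (abs(mu) < 1e-12) NA_real_ else 100 * sdv / mu,
          n = length(v), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phase x sex comparison of phase-averaged metrics
#'
#' One Gaussian LMM per metric: phase mean ~ sex * phase with an individual
#' random intercept; returns the fits and estimated cell means with 95% CIs.
#'
#' @param pm phase means from [phase_means()].
#' @return list with `fits` (named per metric) and `cell_means`
#'   (sex, phase, estimate per metric).
#' @export
phase_sex_comparison <- function(pm) {
  if (length(unique(pm$phase)) < 2) stop("need >= 2 phases for the comparison")
  pm$sex <- factor(pm$sex)
  pm$phase <- factor(pm$phase,
                     levels = c("pre-breeding", "incubation", "rearing"))
  fits <- list(); cells <- list()
  for (mm in c("prop_flight", "range_m", "straightness")) {
    d <- pm[is.finite(pm[[mm]]), ]
    f <- stats::as.formula(paste(mm, "~ sex * phase"))
    fit <- fit_lmm(f, d, group = "individual_id", standardize = FALSE)
    fits[[mm]] <- fit
    grid <- expand.grid(sex = levels(pm$sex),
                        phase = levels(droplevels(d$phase)),
                        KEEP.OUT.ATTRS = FALSE)
    grid$estimate <- predict_response(fit, grid)
    grid$metric <- mm
    cells[[mm]] <- grid
  }
  list(fits = fits, cell_means = do.call(rbind, cells))
}

movement_rhs <- function(with_nloc) {
  paste("~ experience + rain + temp + wind + I(wind^2)",
        if (with_nloc) "+ n_fixes" else "")
}

#' Per-sex x per-phase movement models
#'
#' For each sex x phase cell: a binomial GLMM on (locations in flight,
#' locations not in flight); a Gaussian LMM on log range of movement; and a
#' Gaussian LMM on logit straightness (values at exactly 0/1 nudged into
#' `[eps, 1 - eps]`). Covariates: experience, daily rainfall, daily mean
#' temperature, daily mean wind speed plus its square, all standardized
#' within each model's dataset; the number of locations is added for the
#' range and straightness models only (it already defines the flight
#' proportion's denominator). Individual random intercept throughout.
#'
#' @param daily joined daily table: individual_id, sex, phase, k_flight,
#'   n_fixes, range_m, straightness, experience, rain, temp, wind.
#' @param standardize z-score continuous covariates (default TRUE).
#' @param eps straightness boundary nudge (default 1e-3).
#' @return list of per-cell fit lists (`$flight`, `$range`,
#'   `$straightness`), named "sex.phase", plus `$coefficients` (tidy table
#'   over all converged fits).
#' @export
fit_movement_models <- function(daily, standardize = TRUE, eps = 1e-3) {
  out <- list()
  for (sx in unique(daily$sex)) for (ph in unique(daily$phase)) {
    d <- daily[daily$sex == sx & daily$phase == ph, ]
    if (nrow(d) == 0) next
    if (length(unique(d$individual_id)) < 2) {
      warning(sprintf("cell %s/%s has < 2 individuals; skipped", sx, ph))
      next
    }
    cell <- list()
    cell$flight <- fit_binomial_glmm(
      stats::as.formula(paste("cbind(k_flight, n_fixes - k_flight)",
                              movement_rhs(FALSE))),
      d, group = "individual_id", standardize = standardize)
    dr <- d[is.finite(d$range_m) & d$range_m > 0, ]
    cell$range <- if (nrow(dr) >= 10) fit_lmm(
      stats::as.formula(paste("log(range_m)", movement_rhs(TRUE))),
      dr, group = "individual_id", standardize = standardize) else NULL
    ds <- d[is.finite(d$straightness), ]
    if (nrow(ds) >= 10) {
      ds$str_logit <- stats::qlogis(pmin(1 - eps, pmax(eps, ds$straightness)))
      cell$straightness <- fit_lmm(
        stats::as.formula(paste("str_logit", movement_rhs(TRUE))),
        ds, group = "individual_id", standardize = standardize)
    } else cell$straightness <- NULL
    out[[paste(sx, ph, sep = ".")]] <- cell
  }
  tidy <- list()
  for (nm in names(out)) for (wh in c("flight", "range", "straightness")) {
    f <- out[[nm]][[wh]]
    if (is.null(f) || !f$converged) next
    w <- wald_summary(f)
    w$model <- paste(nm, wh, sep = ".")
    tidy[[length(tidy) + 1]] <- w
  }
  out$coefficients <- if (length(tidy)) do.call(rbind, tidy) else NULL
  out
}

#' Breeding-stage models
#'
#' Three binomial GLMMs with a site random intercept: laying on all events,
#' hatching on the laid subset, fledging on the hatched subset. Fixed
#' effects: recruitment (treatment contrasts, reference level "0" = no
#' recruitment; levels absent from a subset are dropped with a warning) plus
#' the standardized phase weather of the phase preceding each outcome
#' (cumulative rain, min and max of daily mean temperature, windy-day and
#' calm-day counts). Also returns predicted probabilities per recruitment
#' level at average weather.
#'
#' @param events breeding-event table (validated on entry).
#' @param phase_weather data.frame (site_id, year, phase, rain_cum_mm,
#'   temp_min_c, temp_max_c, days_wind_above, days_wind_below).
#' @param which subset of c("laying", "hatching", "fledging") to fit.
#' @return list: `laying`, `hatching`, `fledging` (`cpf_fit`s),
#'   `predicted_laying` (level, probability), `coefficients` (tidy table).
#' @export
fit_breeding_models <- function(events, phase_weather,
                                which = c("laying", "hatching", "fledging")) {
  validate_breeding_events(events)
  join_phase <- function(ev, ph) {
    w <- phase_weather[phase_weather$phase == ph, ]
    i <- match(paste(ev$site_id, ev$year), paste(w$site_id, w$year))
    if (any(is.na(i))) stop("missing ", ph, " weather for some events")
    cbind(ev, w[i, c("rain_cum_mm", "temp_min_c", "temp_max_c",
                     "days_wind_above", "days_wind_below")])
  }
  wx_terms <- "rain_cum_mm + temp_min_c + temp_max_c + days_wind_above + days_wind_below"
  prep <- function(ev, resp) {
    ev$recruitment <- factor(as.character(ev$recruitment),
                             levels = c("0", "F", "M", "MF"))
    present <- levels(droplevels(ev$recruitment))
    dropped <- setdiff(c("0", "F", "M", "MF"), present)
    if (length(dropped)) {
      warning(sprintf("%s model: recruitment level(s) %s absent; dropped",
                      resp, paste(dropped, collapse = ",")))
    }
    ev$recruitment <- droplevels(ev$recruitment)
    ev
  }

  form <- stats::as.formula(paste("cbind(y, 1 - y) ~ recruitment +", wx_terms))
  fits <- list(laying = NULL, hatching = NULL, fledging = NULL)
  pred <- NULL

  if ("laying" %in% which) {
    lay <- prep(join_phase(events, "pre-breeding"), "laying")
    lay$y <- as.integer(lay$laid)
    fits$laying <- fit_binomial_glmm(form, lay, group = "site_id")
    lv <- levels(lay$recruitment)
    nd <- data.frame(recruitment = factor(lv, levels = lv),
                     rain_cum_mm = mean(lay$rain_cum_mm),
                     temp_min_c = mean(lay$temp_min_c),
                     temp_max_c = mean(lay$temp_max_c),
                     days_wind_above = mean(lay$days_wind_above),
                     days_wind_below = mean(lay$days_wind_below))
    pred <- data.frame(level = lv,
                       probability = predict_response(fits$laying, nd),
                       stringsAsFactors = FALSE)
    # model-implied marginal probability per level: average over the level's
    # events of E_u[plogis(eta + u)], u ~ N(0, sigma_u^2) (Gauss-Hermite).
    # Unlike the at-mean-covariates prediction this estimand is free of the
    # Jensen gap, so it is the one to compare against generating frequencies.
    gh <- gauss_hermite(15)
    su <- fits$laying$sigma_u
    p_cond <- predict_response(fits$laying, lay)
    eta <- stats::qlogis(pmin(1 - 1e-12, pmax(1e-12, p_cond)))
    p_marg <- as.numeric(
      vapply(eta, function(e) {
        sum(gh$weights / sqrt(pi) *
              stats::plogis(e + sqrt(2) * su * gh$nodes))
      }, 1))
    pred$marginal_probability <-
      vapply(lv, function(l) mean(p_marg[lay$recruitment == l]), 1)
  }
  if ("hatching" %in% which) {
    hat <- prep(join_phase(events[events$laid, ], "incubation"), "hatching")
    hat$y <- as.integer(hat$hatched)
    fits$hatching <- fit_binomial_glmm(form, hat, group = "site_id")
  }
  if ("fledging" %in% which) {
    fle <- events[events$laid & !is.na(events$hatched) & events$hatched, ]
    fle <- prep(join_phase(fle, "rearing"), "fledging")
    fle$y <- as.integer(fle$fledged)
    fits$fledging <- fit_binomial_glmm(form, fle, group = "site_id")
  }

  tidy <- list()
  for (nm in c("laying", "hatching", "fledging")) {
    f <- fits[[nm]]
    if (!is.null(f) && f$converged) {
      w <- wald_summary(f); w$model <- nm
      tidy[[length(tidy) + 1]] <- w
    }
  }
  list(laying = fits$laying, hatching = fits$hatching,
       fledging = fits$fledging, predicted_laying = pred,
       coefficients = if (length(tidy)) do.call(rbind, tidy) else NULL)
}

#' Movement -> productivity models
#'
#' Per sex x phase x metric: a Gaussian LMM of the fledgling count (0/1/2)
#' on the standardized phase-averaged metric, with a site random intercept.
#' Only individuals tracked through a complete breeding season (all three
#' phases present) are used; cells with fewer than `min_events` events are
#' skipped with a warning.
#'
#' @param pm phase means ([phase_means()]).
#' @param events breeding-event table with male_id/female_id, site_id, year
#'   and n_fledged.
#' @param min_events minimum events per fit (default 5).
#' @return list of `cpf_fit`s named "sex.phase.metric", plus
#'   `$coefficients` (tidy slope table).
#' @export
fit_productivity_models <- function(pm, events, min_events = 5) {
  validate_breeding_events(events)
  full <- names(which(table(pm$individual_id) == 3))
  pm <- pm[pm$individual_id %in% full, ]
  out <- list(); tidy <- list()
  for (sx in c("M", "F")) {
    id_col <- if (sx == "M") "male_id" else "female_id"
    for (ph in unique(pm$phase)) for (mm in c("prop_flight", "range_m", "straightness")) {
      d <- pm[pm$sex == sx & pm$phase == ph & is.finite(pm[[mm]]), ]
      i <- match(events[[id_col]], d$individual_id)
      ev <- events[!is.na(i), ]
      ev$metric <- d[[mm]][i[!is.na(i)]]
      if (nrow(ev) < min_events) {
        warning(sprintf("productivity cell %s/%s/%s has %d events (< %d); skipped",
                        sx, ph, mm, nrow(ev), min_events))
        next
      }
      fit <- fit_lmm(n_fledged ~ metric, ev, group = "site_id",
                     standardize = TRUE)
      nm <- paste(sx, ph, mm, sep = ".")
      out[[nm]] <- fit
      if (fit$converged) {
        w <- wald_summary(fit); w$model <- nm
        tidy[[length(tidy) + 1]] <- w
      }
    }
  }
  out$coefficients <- if (length(tidy)) do.call(rbind, tidy) else NULL
  out
}
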