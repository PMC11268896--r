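#' Wald summary table for a fitted mixed model
#'
#' Per-term estimates, standard errors, two-sided normal z tests and 95%
#' confidence intervals, with the significance tag convention used
#' throughout the analysis battery: `significant` when p < .05, `marginal`
#' when .05 <= p < .1 (a potential but marginal effect), `ns` otherwise.
#'
#' @param fit a converged `cpf_fit`.
#' @return data.frame with columns term, estimate, se, z, p, ci_low, ci_high,
#'   tag.
#' @export
wald_summary <- function(fit) {
  stopifnot(inherits(fit, "cpf_fit"))
  if (!fit$converged) {
    stop("wald_summary(): fit did not converge (", fit$diagnostics,
         "); summaries suppressed")
  }
  est <- fit$coefficients
  se <- fit$se
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(0.975)
  tag <- ifelse(p < 0.05, "significant", ifelse(p < 0.1, "marginal", "ns"))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(p),
             ci_low = unname(est - zc * se), ci_high = unname(est + zc * se),
             tag = unname(tag), row.names = NULL, stringsAsFactors = FALSE)
}

#' Predict the response at a covariate setting
#'
#' Inverse-link of the fixed-effect linear predictor with the random
#' intercept at zero (a population-typical prediction). Covariates that were
#' standardized at fit time are standardized with the stored means and SDs,
#' so `newdata` is given in raw units.
#'
#' @param fit a `cpf_fit`.
#' @param newdata data.frame of covariate settings (raw units).
#' @return numeric vector of response-scale predictions.
#' @export
predict_response <- function(fit, newdata) {
  stopifnot(inherits(fit, "cpf_fit"))
  trm <- stats::delete.response(fit$terms)
  mf <- stats::model.frame(trm, newdata, xlev = fit$xlevels,
                           na.action = stats::na.fail)
  X <- stats::model.matrix(trm, mf)
  for (nm in names(fit$standardizers)) {
    if (nm %in% colnames(X)) {
      X[, nm] <- std_apply(fit$standardizers[[nm]], X[, nm])
    }
  }
  X <- X[, names(fit$coefficients), drop = FALSE]
  eta <- unname(drop(X %*% fit$coefficients))
  switch(fit$kind,
         gaussian = eta,
         binomial = stats::plogis(eta),
         stop("unknown fit kind"))
}

#' Raw-scale vertex of a quadratic wind response
#'
#' For a fit containing `wind` and `I(wind^2)` terms, returns the wind speed
#' (m/s, raw units) at which the fitted quadratic response peaks:
#' `-b1 / (2 b2)` after back-transforming standardized coefficients.
#'
#' @param fit a `cpf_fit` with `wind` and `I(wind^2)` terms.
#' @return wind speed in m/s.
#' @export
wind_vertex <- function(fit) {
  braw <- coef_raw(fit)
  if (!all(c("wind", "I(wind^2)") %in% names(braw))) {
    stop("fit has no wind + I(wind^2) terms")
  }
  -braw[["wind"]] / (2 * braw[["I(wind^2)"]])
}
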