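# Shared design-matrix machinery for the mixed-model engine.
#
# `formula` is a standard R fixed-effects formula; the random intercept is
# declared separately through `group` (a column name), because the engine
# supports exactly one random intercept and nothing else.
build_mixed_design <- function(formula, data, group, standardize = TRUE) {
  if (!is.character(group) || length(group) != 1 || !group %in% names(data)) {
    stop("`group` must name a column of `data`")
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit,
                           drop.unused.levels = TRUE)
  keep <- attr(mf, "na.action")
  g <- data[[group]]
  if (!is.null(keep)) g <- g[-as.integer(keep)]
  g <- factor(g)
  if (nlevels(g) < 2) stop("need >= 2 groups for a random intercept")
  trm <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(trm, mf)

  stds <- list()
  if (standardize) {
    sd_out <- standardize_design(X)
    X <- sd_out$X
    stds <- sd_out$standardizers
  }

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  list(y = y, X = X, g = g, terms = trm,
       xlevels = stats::.getXlevels(trm, mf),
       standardizers = stds, n = nrow(X))
}

new_cpf_fit <- function(kind, des, coefficients, se, vcov, sigma_u, sigma_e,
                        loglik, converged, boundary, diagnostics, extra = list()) {
  structure(c(list(
    kind = kind,
    coefficients = coefficients,
    se = se,
    vcov = vcov,
    sigma_u = sigma_u,
    sigma_e = sigma_e,
    loglik = loglik,
    converged = converged,
    boundary = boundary,
    diagnostics = diagnostics,
    nobs = des$n,
    ngroups = nlevels(des$g),
    terms = des$terms,
    xlevels = des$xlevels,
    standardizers = des$standardizers
  ), extra), class = "cpf_fit")
}

#' @export
print.cpf_fit <- function(x, ...) {
  cat(sprintf("<cpf_fit: %s, random intercept, %d obs in %d groups>\n",
              x$kind, x$nobs, x$ngroups))
  cat(sprintf("  logLik %.4f | sigma_u %.4f%s%s\n", x$loglik, x$sigma_u,
              if (x$kind == "gaussian") sprintf(" | sigma_e %.4f", x$sigma_e) else "",
              if (x$boundary) " (boundary)" else ""))
  if (!x$converged) cat("  WARNING: fit did not converge (", x$diagnostics, ")\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.cpf_fit <- function(object, ...) object$coefficients

#' @export
vcov.cpf_fit <- function(object, ...) object$vcov

#' @export
logLik.cpf_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) +
              if (object$kind == "gaussian") 2L else 1L,
            nobs = object$nobs, class = "logLik")
}

#' Back-transform standardized coefficients to raw covariate units
#'
#' For a fit with internally standardized continuous covariates, returns the
#' coefficient vector on the original (raw) covariate scale:
#' `beta_raw_j = beta_std_j / sd_j`, with the intercept shifted by
#' `sum_j beta_std_j * mean_j / sd_j`.
#'
#' @param fit a `cpf_fit`.
#' @return named numeric vector of raw-scale coefficients.
#' @export
coef_raw <- function(fit) {
  b <- fit$coefficients
  if (length(fit$standardizers) == 0) return(b)
  shift <- 0
  for (nm in names(fit$standardizers)) {
    std <- fit$standardizers[[nm]]
    shift <- shift + b[[nm]] * std$mean / std$sd
    b[[nm]] <- b[[nm]] / std$sd
  }
  if ("(Intercept)" %in% names(b)) {
    b[["(Intercept)"]] <- b[["(Intercept)"]] - shift
  }
  b
}
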