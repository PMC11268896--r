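#' Gaussian linear mixed model with a single random intercept
#'
#' Fits `y ~ fixed effects + (1 | group)` by maximum likelihood (REML
#' optional). For the random-intercept-only case the marginal covariance is
#' block diagonal, `V_g = sigma_e^2 I + sigma_u^2 J`, so the profiled
#' likelihood is evaluated in closed form from per-group sufficient
#' statistics; the two variance components are optimized on the log scale.
#'
#' @param formula fixed-effects formula (response on the left).
#' @param data a data.frame.
#' @param group name of the grouping column for the random intercept.
#' @param standardize logical; z-score continuous covariates (default TRUE).
#'   Factor dummies and the intercept are never standardized.
#' @param reml use REML instead of ML (default FALSE: ML, so nested
#'   fixed-effect comparisons are coherent).
#' @return a `cpf_fit` with coefficients, Wald SEs, `sigma_u`, `sigma_e`,
#'   log-likelihood and convergence diagnostics.
#' @seealso [fit_binomial_glmm()], [wald_summary()], [predict_response()]
#' @export
fit_lmm <- function(formula, data, group, standardize = TRUE, reml = FALSE) {
  des <- build_mixed_design(formula, data, group, standardize = standardize)
  y <- des$y; X <- des$X; g <- des$g
  if (!is.numeric(y)) stop("fit_lmm() needs a numeric response")
  N <- length(y); p <- ncol(X)
  gi <- as.integer(g)
  n_g <- tabulate(gi)
  XtX <- crossprod(X)
  SX <- rowsum(X, gi)                     # G x p group sums
  Sy <- rowsum(y, gi)[, 1]

  # profiled (over beta) marginal log-likelihood at (log su2, log se2)
  prof <- function(theta) {
    su2 <- exp(theta[1]); se2 <- exp(theta[2])
    d <- se2 + n_g * su2
    cg <- su2 / d                         # shrinkage per group
    A <- (XtX - crossprod(SX * cg, SX)) / se2       # X' V^-1 X
    bvec <- (crossprod(X, y) - crossprod(SX, cg * Sy)) / se2
    beta <- solve(A, bvec)
    r <- y - X %*% beta
    Sr <- rowsum(r, gi)[, 1]
    quad <- (sum(r^2) - sum(cg * Sr^2)) / se2
    logdet <- sum((n_g - 1) * log(se2) + log(d))
    ll <- -0.5 * (N * log(2 * pi) + logdet + quad)
    if (reml) {
      ll <- ll - 0.5 * determinant(A, logarithm = TRUE)$modulus[1] +
        0.5 * p * log(2 * pi)
    }
    list(nll = -ll, beta = drop(beta), A = A)
  }

  # moment-based start
  ols <- stats::lm.fit(X, y)
  r0 <- ols$residuals
  vb <- stats::var(rowsum(r0, gi)[, 1] / n_g)
  se2_0 <- max(stats::var(r0) * 0.8, 1e-8)
  su2_0 <- max(vb - se2_0 / mean(n_g), se2_0 * 0.1, 1e-6)
  opt <- stats::nlminb(log(c(su2_0, se2_0)), function(th) prof(th)$nll,
                       lower = c(log(1e-16), log(1e-12)), upper = c(50, 50),
                       control = list(rel.tol = 1e-14, x.tol = 1e-12,
                                      eval.max = 2000, iter.max = 1000))
  at <- prof(opt$par)
  su2 <- exp(opt$par[1]); se2 <- exp(opt$par[2])
  boundary <- su2 < 1e-8
  vc <- solve(at$A)
  se <- sqrt(diag(vc))
  beta <- at$beta
  names(beta) <- names(se) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  converged <- opt$convergence == 0 ||
    grepl("singular convergence|relative convergence|X-convergence",
          opt$message %||% "")
  new_cpf_fit("gaussian", des, beta, se, vc,
              sigma_u = sqrt(su2), sigma_e = sqrt(se2),
              loglik = -at$nll, converged = converged,
              boundary = boundary,
              diagnostics = if (converged) "" else opt$message,
              extra = list(reml = reml))
}
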