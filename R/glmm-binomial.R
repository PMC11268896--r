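# Internal: adaptive Gauss-Hermite marginal log-likelihood machinery for a
# binomial-counts GLMM with one random intercept.
#
# For each group g the integrand is exp(f_g(b)) with
#   f_g(b) = sum_i [k_i eta_i - n_i log(1 + e^{eta_i})] - b^2/(2 su^2)
#            - log(su sqrt(2 pi)),    eta_i = x_i'beta + b.
# The conditional mode b_g is found by (vectorized, step-halved) Newton; the
# Laplace curvature tau_g = (-f_g'')^{-1/2} rescales the GH nodes:
#   log integral ~= log(sqrt(2) tau_g) + logsumexp_j [log w_j + z_j^2 +
#                   f_g(b_g + sqrt(2) tau_g z_j)].
agq_machinery <- function(k, n, X, gi, G, nodes) {
  gh <- gauss_hermite(nodes)
  nq <- length(gh$nodes)
  # sort rows by group once; per-group sums become cumsum differences
  ord <- order(gi)
  k <- k[ord]; n <- n[ord]; X <- X[ord, , drop = FALSE]; gi <- gi[ord]
  ends <- cumsum(tabulate(gi, nbins = G))
  grpsum <- function(v) {
    cs <- cumsum(v)
    c(cs[ends[1]], diff(cs[ends]))
  }
  lchoose_sum <- sum(lchoose(n, k))
  Sk <- grpsum(k)
  b_warm <- new.env(parent = emptyenv())
  b_warm$b <- rep(0, G)

  cond_terms <- function(eta0, bb) {
    # sum_i k_i eta_i - n_i log1pexp(eta_i), per group, at b = bb[g]
    eta <- eta0 + bb[gi]
    grpsum(k * eta - n * log1pexp(eta))
  }

  find_modes <- function(eta0, su2) {
    b <- b_warm$b
    f_at <- function(bb) cond_terms(eta0, bb) - bb^2 / (2 * su2)
    for (it in 1:100) {
      p <- 1 / (1 + exp(-(eta0 + b[gi])))
      score <- Sk - grpsum(n * p) - b / su2
      hess <- -grpsum(n * p * (1 - p)) - 1 / su2
      step <- score / hess
      if (max(abs(step)) < 1e-11) break
      b_new <- b - step
      # Newton on this concave objective only needs guarding for big steps
      if (max(abs(step)) > 0.5) {
        fb <- f_at(b)
        f_new <- f_at(b_new)
        for (h in 1:30) {
          bad <- f_new < fb - 1e-12
          if (!any(bad)) break
          b_new[bad] <- (b_new[bad] + b[bad]) / 2
          f_new <- f_at(b_new)
        }
      }
      b <- b_new
    }
    b_warm$b <- b
    p <- 1 / (1 + exp(-(eta0 + b[gi])))
    list(b = b, neg_hess = grpsum(n * p * (1 - p)) + 1 / su2)
  }

  loglik <- function(beta, sigma_u) {
    su2 <- max(sigma_u^2, 1e-16)
    eta0 <- drop(X %*% beta)
    m <- find_modes(eta0, su2)
    tau <- 1 / sqrt(m$neg_hess)
    # all nodes at once: n x nq matrices
    Bmat <- m$b + sqrt(2) * tau %o% gh$nodes          # G x nq
    ETA <- eta0 + Bmat[gi, , drop = FALSE]
    contrib <- k * ETA - n * log1pexp(ETA)
    fgj <- rowsum(contrib, gi, reorder = FALSE) - Bmat^2 / (2 * su2)
    tmat <- sweep(fgj, 2, log(gh$weights) + gh$nodes^2, "+")
    tmax <- apply(tmat, 1, max)
    ll_g <- log(sqrt(2) * tau) + tmax + log(rowSums(exp(tmat - tmax))) -
      log(sqrt(2 * pi) * sqrt(su2))
    sum(ll_g) + lchoose_sum
  }
  loglik
}

#' Binomial GLMM with a single random intercept (adaptive quadrature)
#'
#' Fits a binomial-counts mixed model, `cbind(successes, failures) ~ fixed
#' effects + (1 | group)`, by maximizing the marginal likelihood in which the
#' Gaussian random intercept is integrated out by adaptive Gauss-Hermite
#' quadrature (15 nodes by default; 1 node is the Laplace approximation).
#' The random-intercept SD is optimized on the log scale; estimates that pin
#' to the lower bound are reported as boundary-zero fits.
#'
#' @inheritParams fit_lmm
#' @param nodes number of quadrature nodes (default 15).
#' @param sigma_u_fixed optional non-negative number: hold the
#'   random-intercept SD fixed at this value instead of estimating it
#'   (0 reduces the model to ordinary logistic regression).
#' @return a `cpf_fit`.
#' @export
fit_binomial_glmm <- function(formula, data, group, standardize = TRUE,
                              nodes = 15, sigma_u_fixed = NULL) {
  des <- build_mixed_design(formula, data, group, standardize = standardize)
  y <- des$y
  if (is.null(dim(y)) || ncol(y) != 2) {
    stop("binomial response must be cbind(successes, failures)")
  }
  k <- y[, 1]; nk <- y[, 2]; ntr <- k + nk
  if (any(k < 0) || any(nk < 0)) stop("negative counts: need 0 <= k <= n")
  if (any(ntr < 1)) stop("each row needs at least one trial")
  X <- des$X; gi <- as.integer(des$g); G <- nlevels(des$g)
  p <- ncol(X)

  ll_fun <- agq_machinery(k, ntr, X, gi, G, nodes)

  # starting values only; glm.fit's own separation warnings are irrelevant
  glm0 <- suppressWarnings(stats::glm.fit(X, cbind(k, nk),
                                          family = stats::binomial()))
  beta0 <- glm0$coefficients
  fixed_su <- !is.null(sigma_u_fixed)
  lsu_lo <- log(1e-8)

  if (fixed_su) {
    su <- sigma_u_fixed
    nll <- function(th) -ll_fun(th, su)
    opt <- stats::nlminb(beta0, nll,
                         control = list(rel.tol = 1e-13, eval.max = 5000,
                                        iter.max = 2000))
    theta <- opt$par
    beta <- theta
    lsu_hat <- log(max(su, 1e-8))
  } else {
    nll <- function(th) -ll_fun(th[1:p], exp(th[p + 1]))
    start <- c(beta0, log(0.5))
    opt <- stats::nlminb(start, nll,
                         lower = c(rep(-Inf, p), lsu_lo),
                         upper = c(rep(Inf, p), log(50)),
                         control = list(rel.tol = 1e-13, eval.max = 5000,
                                        iter.max = 2000))
    theta <- opt$par
    beta <- theta[1:p]
    lsu_hat <- unname(theta[p + 1])
    su <- exp(lsu_hat)
  }
  names(beta) <- colnames(X)
  boundary <- !fixed_su && lsu_hat <= lsu_lo + 1e-6

  # observed information for the fixed effects (sigma_u profiled in the
  # Hessian when estimated and interior)
  H <- try(stats::optimHess(theta, nll), silent = TRUE)
  # "singular convergence" (a flat profile, typical at the sigma_u boundary)
  # still yields a usable stationary point
  converged <- opt$convergence == 0 ||
    grepl("singular convergence|relative convergence|X-convergence",
          opt$message %||% "")
  diagnostics <- if (opt$convergence == 0) "" else opt$message
  vc <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  se <- rep(NA_real_, p); names(se) <- colnames(X)
  if (!inherits(H, "try-error")) {
    Hb <- if (fixed_su || boundary) H[1:p, 1:p, drop = FALSE] else H
    vfull <- try(solve(Hb), silent = TRUE)
    if (!inherits(vfull, "try-error") && all(diag(vfull)[1:p] > 0)) {
      vc <- vfull[1:p, 1:p, drop = FALSE]
      dimnames(vc) <- list(colnames(X), colnames(X))
      se <- sqrt(diag(vc))
    } else {
      converged <- FALSE
      diagnostics <- paste(diagnostics, "singular information (possible complete separation)")
    }
  }
  if (any(abs(beta) > 15)) {
    converged <- FALSE
    diagnostics <- paste(diagnostics, "extreme coefficients (possible complete separation)")
  }

  new_cpf_fit("binomial", des, beta, se, vc,
              sigma_u = if (boundary) 0 else su, sigma_e = NA_real_,
              loglik = -opt$objective, converged = converged,
              boundary = boundary, diagnostics = trimws(diagnostics),
              extra = list(nodes = nodes,
                           loglik_fun = ll_fun))
}

#' Marginal log-likelihood of a binomial random-intercept GLMM
#'
#' Evaluates the adaptive-quadrature marginal log-likelihood at user-supplied
#' parameter values, without fitting. Intended for validation against
#' independent brute-force integration.
#'
#' @inheritParams fit_binomial_glmm
#' @param beta fixed-effect vector (in the order of the model matrix columns).
#' @param sigma_u random-intercept SD (>= 0).
#' @return a single number, the marginal log-likelihood (including the
#'   binomial normalizing constants).
#' @export
binomial_glmm_loglik <- function(formula, data, group, beta, sigma_u,
                                 nodes = 15, standardize = FALSE) {
  des <- build_mixed_design(formula, data, group, standardize = standardize)
  y <- des$y
  k <- y[, 1]; ntr <- y[, 1] + y[, 2]
  ll_fun <- agq_machinery(k, ntr, des$X, as.integer(des$g), nlevels(des$g), nodes)
  ll_fun(beta, sigma_u)
}
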