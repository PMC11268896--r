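#' Standardize a covariate to zero mean and unit sample SD
#'
#' Centres and scales `x` as z = (x - mean(x)) / sd(x), with the sample
#' (n - 1) standard deviation. The returned standardizer records the mean
#' and SD captured at call time so the transform can be replayed on new data
#' or inverted exactly.
#'
#' @param x numeric vector with at least 2 distinct finite values.
#' @return list with elements `z` (the standardized vector) and `standardizer`
#'   (class `cpf_standardizer`: list with `mean` and `sd`).
#' @export
#' @examples
#' standardize(c(1, 2, 3))$z   # -1 0 1
standardize <- function(x) {
  if (!is.numeric(x)) stop("standardize() needs a numeric vector")
  xf <- x[is.finite(x)]
  if (length(unique(xf)) < 2) stop("standardize(): constant vector (needs >= 2 distinct values)")
  m <- mean(xf)
  s <- stats::sd(xf)
  std <- structure(list(mean = m, sd = s), class = "cpf_standardizer")
  list(z = (x - m) / s, standardizer = std)
}

#' Apply or invert a stored standardizer
#' @param std a `cpf_standardizer`.
#' @param x numeric vector.
#' @return transformed numeric vector.
#' @export
std_apply <- function(std, x) (x - std$mean) / std$sd

#' @rdname std_apply
#' @export
std_invert <- function(std, x) x * std$sd + std$mean

# Standardize the non-intercept, non-indicator columns of a design matrix.
# Binary 0/1 columns (factor dummies) and the intercept are left alone,
# matching the field convention of z-scoring continuous covariates only.
# Returns list(X, standardizers).
standardize_design <- function(X) {
  stds <- list()
  for (j in seq_len(ncol(X))) {
    nm <- colnames(X)[j]
    v <- X[, j]
    u <- unique(v)
    if (nm == "(Intercept)") next
    if (length(u) <= 2 && all(u %in% c(0, 1))) next
    if (length(unique(v)) < 2) next   # constant column: leave for rank check
    s <- standardize(v)
    X[, j] <- s$z
    stds[[nm]] <- s$standardizer
  }
  list(X = X, standardizers = stds)
}
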