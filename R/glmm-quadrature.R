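# Gauss-Hermite nodes and weights (physicists' convention):
#   integral exp(-x^2) f(x) dx = sum_j w_j f(x_j)
# computed by the Golub-Welsch eigen decomposition of the Jacobi matrix.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log(1 + exp(x)) without overflow (branchless, works on matrices)
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}
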