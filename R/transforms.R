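# Canonical-partial-correlation (C-vine) parameterization of a correlation
# Cholesky factor, and the matching LKJ prior terms.  With unconstrained y,
# z = tanh(y), the implied correlation matrix has exactly the LKJ(eta)
# density when each column-j entry carries a Beta-type term with shape
# eta + (K - 1 - j)/2 (Lewandowski-Kurowicka-Joe vine construction), and all
# gradients are closed-form.

# index helper: entries ordered row-wise, rows i = 2..K, cols j = 1..i-1
.cpc_len <- function(K) K * (K - 1L) / 2L

#' Cholesky factor of a correlation matrix from canonical partial correlations
#' @param z numeric vector of length `K*(K-1)/2` with entries in (-1, 1),
#'   ordered row-wise (row 2 first).
#' @param K matrix dimension.
#' @return lower-triangular `K x K` Cholesky factor with unit row norms.
#' @keywords internal
cpc_chol <- function(z, K) {
  L <- diag(1, K)
  pos <- 0L
  for (i in seq_len(K)[-1]) {
    prod_c <- 1
    for (j in seq_len(i - 1L)) {
      pos <- pos + 1L
      L[i, j] <- z[pos] * prod_c
      prod_c <- prod_c * sqrt(1 - z[pos]^2)
    }
    L[i, i] <- prod_c
  }
  L
}

# log density (up to a constant) of the LKJ(eta) prior in the unconstrained
# y-parameterization, tanh Jacobian included; plus its gradient wrt y.
.lkj_alpha <- function(K, eta) {
  a <- numeric(.cpc_len(K))
  pos <- 0L
  for (i in seq_len(K)[-1]) {
    for (j in seq_len(i - 1L)) {
      pos <- pos + 1L
      a[pos] <- eta + (K - 1 - j) / 2
    }
  }
  a
}

lkj_cpc_logprior <- function(y, K, eta = 2) {
  z <- tanh(y)
  sum(.lkj_alpha(K, eta) * log1p(-z^2))
}

lkj_cpc_logprior_grad <- function(y, K, eta = 2) {
  -2 * .lkj_alpha(K, eta) * tanh(y)
}

# Backpropagate a gradient wrt the Cholesky factor L to the unconstrained y.
# GL is a K x K matrix whose lower triangle (incl. diagonal) holds
# d logp / d L[i,j]; entries above the diagonal are ignored.
cpc_chol_grad <- function(y, K, GL) {
  z <- tanh(y)
  gz <- numeric(length(z))
  pos0 <- 0L
  for (i in seq_len(K)[-1]) {
    m <- i - 1L
    zi <- z[pos0 + seq_len(m)]
    ci2 <- 1 - zi^2
    # prefix products of sqrt(1 - z^2)
    P <- c(1, cumprod(sqrt(ci2)))   # P[j] = prod_{k<j} c_k  (1-based: P[1]=1)
    Lrow <- zi * P[seq_len(m)]
    Ldiag <- P[m + 1L]
    for (k in seq_len(m)) {
      g <- GL[i, k] * P[k]
      fac <- -zi[k] / ci2[k]
      jj <- if (k < m) (k + 1L):m else integer(0)
      if (length(jj)) g <- g + sum(GL[i, jj] * Lrow[jj]) * fac
      g <- g + GL[i, i] * Ldiag * fac
      gz[pos0 + k] <- g
    }
    pos0 <- pos0 + m
  }
  gz * (1 - z^2)   # dz/dy
}

#' Draw a correlation-matrix Cholesky factor from the LKJ distribution
#' @param K dimension; `eta` shape (>= 1 concentrates near identity).
#' @return lower-triangular Cholesky factor.
#' @keywords internal
rlkj_chol <- function(K, eta = 2) {
  a <- .lkj_alpha(K, eta)
  z <- 2 * stats::rbeta(length(a), a, a) - 1
  cpc_chol(z, K)
}

# half-Cauchy(0, 1) prior on a scale, in log-scale parameterization
# (Jacobian included)
halfcauchy_logprior <- function(lsigma) {
  s2 <- exp(2 * lsigma)
  sum(log(2 / pi) - log1p(s2) + lsigma)
}

halfcauchy_logprior_grad <- function(lsigma) {
  s2 <- exp(2 * lsigma)
  1 - 2 * s2 / (1 + s2)
}
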