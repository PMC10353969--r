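# Hierarchical multinomial logit for postmarital residence: log odds of each
# non-reference residence type, relative to the reference (equilocal by
# default), with correlated family and male/female birthplace varying
# intercept triples.

#' Linear predictors of the three non-reference residence types
#'
#' `eta_r = x_c' delta_r + W[l(c), r] + Y[b_m(c), r] + Z[b_f(c), r]`; the
#' implicit linear predictor of the reference type is 0.
#'
#' @param params list with `delta` (`K x 3` matrix, or length-`3K`
#'   concatenated vector, columns/blocks in `design$type_levels[-1]` order)
#'   and optional `W`, `Y`, `Z` matrices (`levels x 3`); missing intercepts
#'   default to zero.
#' @param design a [build_residence_design()] object.
#' @param couple optional couple index (row); default all couples.
#' @return matrix (couples x 3) of linear predictors.
#' @export
residence_linpreds <- function(params, design, couple = NULL) {
  K <- ncol(design$X)
  D <- params$delta
  if (is.null(dim(D))) D <- matrix(D, K, 3)
  n <- nrow(design$X)
  zero <- function(m, nr) if (is.null(m)) matrix(0, nr, 3) else m
  W <- zero(params$W, length(design$family_levels))
  Y <- zero(params$Y, length(design$male_levels))
  Z <- zero(params$Z, length(design$female_levels))
  eta <- design$X %*% D + W[design$family, , drop = FALSE] +
    Y[design$male_place, , drop = FALSE] +
    Z[design$female_place, , drop = FALSE]
  colnames(eta) <- design$type_levels[-1]
  if (!is.null(couple)) eta[couple, , drop = FALSE] else eta
}

#' Residence-type probabilities from linear predictors
#'
#' Softmax over `(0, eta)`, computed with a log-sum-exp guard; the first
#' column is the reference type.
#'
#' @param linpreds numeric vector of length 3 or matrix (couples x 3).
#' @return matrix (couples x 4) of probabilities summing to 1 per row.
#' @export
residence_probs <- function(linpreds) {
  eta <- if (is.null(dim(linpreds))) matrix(linpreds, 1) else linpreds
  full <- cbind(0, eta)
  m <- apply(full, 1, max)
  e <- exp(full - m)
  p <- e / rowSums(e)
  colnames(p) <- if (!is.null(colnames(eta))) c("reference", colnames(eta)) else NULL
  p
}

#' Multi-logit log-likelihood at natural-scale parameters
#' @inheritParams residence_linpreds
#' @return list with `total` and `pointwise` log-likelihood.
#' @export
residence_loglik <- function(params, design) {
  eta <- residence_linpreds(params, design)
  h <- .mlogit_ll(eta, design$y, deriv = FALSE)
  list(total = sum(h$ll), pointwise = h$ll)
}

# grouped multi-logit log-likelihood; y in 1..4 with 1 = reference
.mlogit_ll <- function(eta, y, deriv = TRUE) {
  m <- pmax(0, eta[, 1], eta[, 2], eta[, 3])
  lse <- m + log(exp(-m) + exp(eta[, 1] - m) + exp(eta[, 2] - m) +
                   exp(eta[, 3] - m))
  pick <- cbind(seq_along(y), pmax(y - 1L, 1L))
  ll <- ifelse(y == 1L, 0, eta[pick]) - lse
  G <- NULL
  if (deriv) {
    G <- exp(eta - lse)          # p_r for the three non-reference types
    G <- -G
    obs <- y > 1L
    G[cbind(which(obs), y[obs] - 1L)] <- G[cbind(which(obs), y[obs] - 1L)] + 1
  }
  list(ll = ll, G = G)
}

#' Multi-logit log-prior at natural-scale parameters
#'
#' Multivariate Gaussian prior (mean 0) on the concatenated coefficient
#' vector `delta`, and zero-mean trivariate Gaussian priors with a shared
#' 3 x 3 covariance on each family (`W`) and male/female birthplace (`Y`,
#' `Z`) intercept triple; covariances decompose into half-Cauchy(0,1) scales
#' and LKJ correlations.
#'
#' @param params list with `delta` and optional `W`, `Y`, `Z`; covariance
#'   decompositions `tau_delta`/`L_delta` and `tau_W`/`L_W` etc. default to
#'   unit scales and identity correlations.
#' @param eta_lkj LKJ shape.
#' @return scalar log-prior; `-Inf` outside the support.
#' @export
residence_logprior <- function(params, eta_lkj = 2) {
  d <- as.numeric(params$delta)
  Kd <- length(d)
  tau_d <- if (is.null(params$tau_delta)) rep(1, Kd) else params$tau_delta
  if (any(tau_d <= 0)) return(-Inf)
  L_d <- if (is.null(params$L_delta)) diag(Kd) else params$L_delta
  lkj_chol <- function(L, eta) {
    sum((nrow(L) - seq_len(nrow(L)) + 2 * eta - 2) * log(diag(L)))
  }
  z <- forwardsolve(L_d, d / tau_d)
  lp <- -0.5 * sum(z^2) - sum(log(tau_d)) - sum(log(diag(L_d))) -
    0.5 * Kd * log(2 * pi) + lkj_chol(L_d, eta_lkj) +
    halfcauchy_logprior(log(tau_d)) - sum(log(tau_d))
  for (blk in c("W", "Y", "Z")) {
    M <- params[[blk]]
    if (is.null(M)) next
    tau <- params[[paste0("tau_", blk)]]
    if (is.null(tau)) tau <- rep(1, 3)
    if (any(tau <= 0)) return(-Inf)
    Lc <- params[[paste0("L_", blk)]]
    if (is.null(Lc)) Lc <- diag(3)
    Zm <- forwardsolve(Lc, t(M) / tau)
    lp <- lp - 0.5 * sum(Zm^2) -
      nrow(M) * (sum(log(tau)) + sum(log(diag(Lc))) + 1.5 * log(2 * pi)) +
      lkj_chol(Lc, eta_lkj) + halfcauchy_logprior(log(tau)) - sum(log(tau))
  }
  lp
}

#' Assemble the residence multi-logit model for fitting
#'
#' Unconstrained parameterization mirroring [migration_model()]: the
#' concatenated coefficient vector is non-centred through its
#' scale/correlation decomposition, and the family and birthplace intercept
#' triples are non-centred through shared 3 x 3 covariance factors.
#'
#' @param design a [build_residence_design()] object.
#' @param eta_lkj LKJ shape.
#' @param backend `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation).
#' @return object of class `kinloc_model`.
#' @export
residence_model <- function(design, eta_lkj = 2, backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  K <- ncol(design$X); Kd <- 3L * K; Kdc <- .cpc_len(Kd)
  L <- length(design$family_levels)
  Bm <- length(design$male_levels); Bf <- length(design$female_levels)
  lens <- c(yd = Kdc, ltd = Kd, delta = Kd,
            yW = 3, ltW = 3, zW = 3 * L,
            yY = 3, ltY = 3, zY = 3 * Bm,
            yZ = 3, ltZ = 3, zZ = 3 * Bf)
  off <- cumsum(c(0, lens))
  ix <- lapply(seq_along(lens), function(i) off[i] + seq_len(lens[i]))
  names(ix) <- names(lens)
  npar <- sum(lens)
  X <- design$X; li <- design$family
  mi <- design$male_place; fi <- design$female_place
  y <- design$y
  xn <- colnames(X); tn <- design$type_levels[-1]
  mod <- list(kind = "residence", design = design, K = K, L = L,
              Bm = Bm, Bf = Bf, n = nrow(X), npar = npar, ix = ix,
              eta_lkj = eta_lkj, backend = backend)
  # one varying-intercept block: value, contribution to eta, gradients
  blk_eval <- function(yc, lt, zmat) {
    tau <- exp(lt)
    Lc <- cpc_chol(tanh(yc), 3)
    A <- tau * Lc                    # diag(tau) %*% Lc
    list(val = zmat %*% t(A), A = A, Lc = Lc, tau = tau)
  }
  eval_r <- function(theta) {
    yd <- theta[ix$yd]; ltd <- theta[ix$ltd]; delta <- theta[ix$delta]
    Ld <- cpc_chol(tanh(yd), Kd)
    Dm <- matrix(delta, K, 3)
    zW <- matrix(theta[ix$zW], L, 3)
    zY <- matrix(theta[ix$zY], Bm, 3)
    zZ <- matrix(theta[ix$zZ], Bf, 3)
    bW <- blk_eval(theta[ix$yW], theta[ix$ltW], zW)
    bY <- blk_eval(theta[ix$yY], theta[ix$ltY], zY)
    bZ <- blk_eval(theta[ix$yZ], theta[ix$ltZ], zZ)
    eta <- X %*% Dm + bW$val[li, , drop = FALSE] +
      bY$val[mi, , drop = FALSE] + bZ$val[fi, , drop = FALSE]
    h <- .mlogit_ll(eta, y)
    md <- .mvn_centred_r(delta, 0, ltd, Ld)
    lp <- sum(h$ll) + md$lp -
      0.5 * (sum(zW^2) + sum(zY^2) + sum(zZ^2)) +
      lkj_cpc_logprior(yd, Kd, eta_lkj) +
      lkj_cpc_logprior(theta[ix$yW], 3, eta_lkj) +
      lkj_cpc_logprior(theta[ix$yY], 3, eta_lkj) +
      lkj_cpc_logprior(theta[ix$yZ], 3, eta_lkj) +
      halfcauchy_logprior(c(ltd, theta[ix$ltW], theta[ix$ltY], theta[ix$ltZ]))
    g <- numeric(npar)
    gD <- crossprod(X, h$G)                      # K x 3
    gd <- as.numeric(gD)
    g[ix$delta] <- gd + md$gx
    g[ix$ltd] <- md$glt + halfcauchy_logprior_grad(ltd)
    g[ix$yd] <- cpc_chol_grad(yd, Kd, md$GL) +
      lkj_cpc_logprior_grad(yd, Kd, eta_lkj)
    blk_grad <- function(b, gM, zmat, iy, ilt, iz, yc, lt) {
      dZ <- gM %*% b$A                           # levels x 3
      dA <- crossprod(gM, zmat)                  # 3 x 3
      g[iz] <<- as.numeric(dZ) - as.numeric(zmat)
      g[ilt] <<- rowSums(dA * b$A) + halfcauchy_logprior_grad(lt)
      g[iy] <<- cpc_chol_grad(yc, 3, b$tau * dA) +
        lkj_cpc_logprior_grad(yc, 3, eta_lkj)
    }
    gW <- rowsum(h$G, li); GW <- matrix(0, L, 3); GW[as.integer(rownames(gW)), ] <- gW
    gY <- rowsum(h$G, mi); GY <- matrix(0, Bm, 3); GY[as.integer(rownames(gY)), ] <- gY
    gZ <- rowsum(h$G, fi); GZ <- matrix(0, Bf, 3); GZ[as.integer(rownames(gZ)), ] <- gZ
    blk_grad(bW, GW, zW, ix$yW, ix$ltW, ix$zW, theta[ix$yW], theta[ix$ltW])
    blk_grad(bY, GY, zY, ix$yY, ix$ltY, ix$zY, theta[ix$yY], theta[ix$ltY])
    blk_grad(bZ, GZ, zZ, ix$yZ, ix$ltZ, ix$zZ, theta[ix$yZ], theta[ix$ltZ])
    list(lp = lp, grad = g, ll = h$ll)
  }
  mod$eval <- if (backend == "cpp") {
    Xt <- t(X)
    function(theta) .res_eval_cpp(theta, Xt, li, mi, fi, y, L, Bm, Bf, eta_lkj)
  } else {
    eval_r
  }
  mod$natural <- function(theta) {
    delta <- theta[ix$delta]
    Wv <- matrix(theta[ix$zW], L, 3) %*%
      t(exp(theta[ix$ltW]) * cpc_chol(tanh(theta[ix$yW]), 3))
    Yv <- matrix(theta[ix$zY], Bm, 3) %*%
      t(exp(theta[ix$ltY]) * cpc_chol(tanh(theta[ix$yY]), 3))
    Zv <- matrix(theta[ix$zZ], Bf, 3) %*%
      t(exp(theta[ix$ltZ]) * cpc_chol(tanh(theta[ix$yZ]), 3))
    stats::setNames(
      c(delta, exp(theta[ix$ltW]), exp(theta[ix$ltY]), exp(theta[ix$ltZ]),
        as.numeric(Wv), as.numeric(Yv), as.numeric(Zv)),
      c(paste0("delta.", rep(tn, each = K), ".", rep(xn, 3)),
        paste0("sigma_W.", tn), paste0("sigma_Y.", tn), paste0("sigma_Z.", tn),
        paste0("W.", rep(tn, each = L), ".", rep(design$family_levels, 3)),
        paste0("Y.", rep(tn, each = Bm), ".", rep(design$male_levels, 3)),
        paste0("Z.", rep(tn, each = Bf), ".", rep(design$female_levels, 3))))
  }
  mod$natural_names <- names(mod$natural(numeric(npar)))
  mod$init <- function(rng_scale = 0.1) stats::rnorm(npar, 0, rng_scale)
  class(mod) <- "kinloc_model"
  mod
}

#' Reference-category change-of-basis matrix
#'
#' Returns the 3 x 3 matrix `M` mapping coefficient (or intercept) triples
#' expressed against `from` type levels to triples against `to` type levels,
#' such that fitted probabilities are unchanged.
#'
#' @param from,to character vectors of 4 type levels, reference first.
#' @return 3 x 3 numeric matrix.
#' @export
reref_matrix <- function(from, to) {
  stopifnot(setequal(from, to), length(from) == 4)
  M <- matrix(0, 3, 3, dimnames = list(to[-1], from[-1]))
  for (r in to[-1]) {
    # eta'_r = eta_r - eta_{to_ref}, with eta_{from_ref} = 0
    if (r != from[1]) M[r, r] <- 1
    if (to[1] != from[1]) M[r, to[1]] <- M[r, to[1]] - 1
  }
  M
}

#' Maximum a posteriori fit of the residence model with fixed covariances
#'
#' Optimizes coefficients and varying intercepts under multivariate Gaussian
#' priors with *given* covariance matrices (no hyperpriors).  Used for
#' algebraic checks such as reference-category invariance, where the prior
#' must transform deterministically with the parameterization.
#'
#' @param design a [build_residence_design()] object.
#' @param Sigma list with covariance matrices `delta` (`3K x 3K`) and `W`,
#'   `Y`, `Z` (`3 x 3`); defaults are identity matrices scaled by 2.
#' @param init optional start vector.
#' @param maxit optimizer iteration cap.
#' @return list with natural-scale `delta`, `W`, `Y`, `Z`, fitted
#'   probabilities `probs` (couples x 4, reference first) and optimizer info.
#' @export
residence_map <- function(design, Sigma = NULL, init = NULL, maxit = 2000L) {
  K <- ncol(design$X); Kd <- 3L * K
  L <- length(design$family_levels)
  Bm <- length(design$male_levels); Bf <- length(design$female_levels)
  if (is.null(Sigma)) Sigma <- list()
  Sd <- if (is.null(Sigma$delta)) diag(2, Kd) else Sigma$delta
  SW <- if (is.null(Sigma$W)) diag(2, 3) else Sigma$W
  SY <- if (is.null(Sigma$Y)) diag(2, 3) else Sigma$Y
  SZ <- if (is.null(Sigma$Z)) diag(2, 3) else Sigma$Z
  Qd <- solve(Sd); QW <- solve(SW); QY <- solve(SY); QZ <- solve(SZ)
  lens <- c(delta = Kd, W = 3 * L, Y = 3 * Bm, Z = 3 * Bf)
  off <- cumsum(c(0, lens))
  ix <- lapply(seq_along(lens), function(i) off[i] + seq_len(lens[i]))
  names(ix) <- names(lens)
  unpack <- function(th) list(
    delta = matrix(th[ix$delta], K, 3),
    W = matrix(th[ix$W], L, 3),
    Y = matrix(th[ix$Y], Bm, 3),
    Z = matrix(th[ix$Z], Bf, 3))
  obj <- function(th) {
    p <- unpack(th)
    eta <- residence_linpreds(p, design)
    h <- .mlogit_ll(eta, design$y, deriv = FALSE)
    -(sum(h$ll) - 0.5 * drop(th[ix$delta] %*% Qd %*% th[ix$delta]) -
        0.5 * sum((p$W %*% QW) * p$W) - 0.5 * sum((p$Y %*% QY) * p$Y) -
        0.5 * sum((p$Z %*% QZ) * p$Z))
  }
  grd <- function(th) {
    p <- unpack(th)
    eta <- residence_linpreds(p, design)
    h <- .mlogit_ll(eta, design$y)
    g <- numeric(length(th))
    g[ix$delta] <- as.numeric(crossprod(design$X, h$G)) -
      drop(Qd %*% th[ix$delta])
    gsum <- function(G, idx, nlev) {
      rs <- rowsum(G, idx); M <- matrix(0, nlev, 3)
      M[as.integer(rownames(rs)), ] <- rs
      M
    }
    g[ix$W] <- as.numeric(gsum(h$G, design$family, L) - p$W %*% QW)
    g[ix$Y] <- as.numeric(gsum(h$G, design$male_place, Bm) - p$Y %*% QY)
    g[ix$Z] <- as.numeric(gsum(h$G, design$female_place, Bf) - p$Z %*% QZ)
    -g
  }
  th0 <- if (is.null(init)) numeric(sum(lens)) else init
  fit <- stats::optim(th0, obj, grd, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  p <- unpack(fit$par)
  probs <- residence_probs(residence_linpreds(p, design))
  c(p, list(probs = probs, value = -fit$value, convergence = fit$convergence))
}
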