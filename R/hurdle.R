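# Two-part (hurdle) migration model: a logistic sub-model for whether a
# family member migrated and a log-normal sub-model for how far, with
# interval censoring integrated out and crossed family/birthplace varying
# intercepts on both parts.

# stable log(pnorm(b) - pnorm(a)) for a < b
.lognormdiff <- function(a, b) {
  out <- numeric(length(a))
  up <- a > 0
  if (any(!up)) {
    l1 <- stats::pnorm(b[!up], log.p = TRUE)
    l2 <- stats::pnorm(a[!up], log.p = TRUE)
    out[!up] <- l1 + log1p(-exp(l2 - l1))
  }
  if (any(up)) {
    l1 <- stats::pnorm(a[up], lower.tail = FALSE, log.p = TRUE)
    l2 <- stats::pnorm(b[up], lower.tail = FALSE, log.p = TRUE)
    out[up] <- l1 + log1p(-exp(l2 - l1))
  }
  out
}

#' Hurdle log-density of one migration outcome
#'
#' The migration distance `d >= 0` has density `1 - pi` at `d = 0` and
#' `pi * g(d)` for `d > 0`, where `pi = plogis(eta)` and `g` is log-normal
#' with location `mu` and scale `sigma_e`.  Censored outcomes contribute the
#' integral of the density over their interval: `interval_censored` outcomes
#' are known migrations with distance in `(d_min, d_max)`;
#' `status_unknown_censored` outcomes have a latent migration indicator and
#' contribute `(1 - pi) + pi * P(d <= d_max)`.
#'
#' @param status one of `observed`, `interval_censored`,
#'   `status_unknown_censored` (vectorized).
#' @param d observed distance in km (`observed` only).
#' @param d_min,d_max censoring bounds in km.
#' @param eta log-odds of migration.
#' @param mu mean log-distance.
#' @param sigma_e residual scale of the log-distance, > 0.
#' @return log-probability (density) per outcome.
#' @export
hurdle_logdensity <- function(status, d = NA_real_, d_min = NA_real_,
                              d_max = NA_real_, eta, mu, sigma_e) {
  if (any(sigma_e <= 0)) stop("sigma_e must be positive")
  n <- max(length(status), length(eta), length(mu))
  status <- rep_len(status, n); d <- rep_len(d, n)
  d_min <- rep_len(d_min, n); d_max <- rep_len(d_max, n)
  eta <- rep_len(eta, n); mu <- rep_len(mu, n)
  sigma_e <- rep_len(sigma_e, n)
  lpi <- stats::plogis(eta, log.p = TRUE)
  lqi <- stats::plogis(-eta, log.p = TRUE)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- switch(
      status[i],
      observed = {
        if (is.na(d[i]) || d[i] < 0) stop("observed outcome needs d >= 0")
        if (d[i] == 0) lqi[i] else
          lpi[i] + stats::dlnorm(d[i], mu[i], sigma_e[i], log = TRUE)
      },
      interval_censored = {
        if (!(d_min[i] > 0) || d_min[i] >= d_max[i]) {
          stop("interval_censored needs 0 < d_min < d_max")
        }
        a <- (log(d_min[i]) - mu[i]) / sigma_e[i]
        b <- (log(d_max[i]) - mu[i]) / sigma_e[i]
        lpi[i] + .lognormdiff(a, b)
      },
      status_unknown_censored = {
        if (!(d_max[i] > 0)) stop("status_unknown_censored needs d_max > 0")
        b <- (log(d_max[i]) - mu[i]) / sigma_e[i]
        l2 <- lpi[i] + stats::pnorm(b, log.p = TRUE)
        m <- max(lqi[i], l2)
        m + log(exp(lqi[i] - m) + exp(l2 - m))
      },
      stop("unknown status: ", status[i])
    )
  }
  out
}

# precomputed censoring/observation groups for fast likelihood evaluation
.mig_groups <- function(o) {
  st <- o$status
  i0 <- which(st == "observed" & o$d == 0)
  ip <- which(st == "observed" & o$d > 0)
  ic <- which(st == "interval_censored")
  iu <- which(st == "status_unknown_censored")
  if (length(ic) && any(!(o$d_min[ic] > 0) | o$d_min[ic] >= o$d_max[ic])) {
    stop("interval_censored outcomes need 0 < d_min < d_max")
  }
  if (length(iu) && any(!(o$d_max[iu] > 0))) {
    stop("status_unknown_censored outcomes need d_max > 0")
  }
  list(i0 = i0, ip = ip, ic = ic, iu = iu,
       logd = log(o$d[ip]),
       la = log(o$d_min[ic]), lb = log(o$d_max[ic]),
       lbu = log(o$d_max[iu]))
}

# grouped hurdle log-likelihood with per-outcome derivatives wrt eta, mu and
# log sigma_e; shared by migration_loglik and the sampler path
.hurdle_ll <- function(eta, mu, sE, gr, deriv = TRUE) {
  n <- length(eta)
  lpi <- stats::plogis(eta, log.p = TRUE)
  lqi <- stats::plogis(-eta, log.p = TRUE)
  pii <- stats::plogis(eta)
  ll <- numeric(n); ge <- numeric(n); gm <- numeric(n); glsE <- 0
  if (length(gr$i0)) {
    ll[gr$i0] <- lqi[gr$i0]
    ge[gr$i0] <- -pii[gr$i0]
  }
  if (length(gr$ip)) {
    r <- (gr$logd - mu[gr$ip]) / sE
    ll[gr$ip] <- lpi[gr$ip] - gr$logd - log(sE) - 0.5 * log(2 * pi) - 0.5 * r^2
    if (deriv) {
      ge[gr$ip] <- 1 - pii[gr$ip]
      gm[gr$ip] <- r / sE
      glsE <- glsE + sum(r^2 - 1)
    }
  }
  if (length(gr$ic)) {
    a <- (gr$la - mu[gr$ic]) / sE
    b <- (gr$lb - mu[gr$ic]) / sE
    logD <- .lognormdiff(a, b)
    ll[gr$ic] <- lpi[gr$ic] + logD
    if (deriv) {
      # log-scale ratios: stable when the interval lies far in the tail
      ra <- exp(stats::dnorm(a, log = TRUE) - logD)
      rb <- exp(stats::dnorm(b, log = TRUE) - logD)
      ge[gr$ic] <- 1 - pii[gr$ic]
      gm[gr$ic] <- (ra - rb) / sE
      glsE <- glsE + sum(a * ra - b * rb)
    }
  }
  if (length(gr$iu)) {
    b <- (gr$lbu - mu[gr$iu]) / sE
    lPhi <- stats::pnorm(b, log.p = TRUE)
    l1 <- lqi[gr$iu]; l2 <- lpi[gr$iu] + lPhi
    m <- pmax(l1, l2)
    lw <- m + log(exp(l1 - m) + exp(l2 - m))
    ll[gr$iu] <- lw
    if (deriv) {
      q1 <- exp(l1 - lw); q2 <- exp(l2 - lw)
      im <- exp(stats::dnorm(b, log = TRUE) - lPhi)  # inverse Mills ratio
      im[q2 == 0] <- 0
      p_u <- pii[gr$iu]
      ge[gr$iu] <- (1 - p_u) * q2 - p_u * q1
      gm[gr$iu] <- -q2 * im / sE
      glsE <- glsE + sum(-q2 * im * b)
    }
  }
  list(ll = ll, ge = ge, gm = gm, glsE = glsE)
}

#' Hurdle model log-likelihood at natural-scale parameters
#'
#' @param params list with `beta`, `gamma` (regression coefficients for the
#'   two sub-models), `S`, `T`, `U`, `V` (family/birthplace varying
#'   intercepts, indexed like the design's levels) and `sigma_e`.  Missing
#'   intercept vectors default to zero.
#' @param design a [build_migration_design()] object.
#' @return list with the `total` log-likelihood and the `pointwise` vector
#'   (retained for PSIS-LOO).
#' @export
migration_loglik <- function(params, design) {
  n <- nrow(design$X)
  L <- length(design$family_levels); B <- length(design$place_levels)
  S <- if (is.null(params$S)) numeric(L) else params$S
  TT <- if (is.null(params$T)) numeric(B) else params$T
  U <- if (is.null(params$U)) numeric(L) else params$U
  V <- if (is.null(params$V)) numeric(B) else params$V
  eta <- drop(design$X %*% params$beta) + S[design$family] + TT[design$place]
  mu <- drop(design$X %*% params$gamma) + U[design$family] + V[design$place]
  gr <- .mig_groups(design$outcomes)
  h <- .hurdle_ll(eta, mu, params$sigma_e, gr, deriv = FALSE)
  list(total = sum(h$ll), pointwise = h$ll)
}

#' Hurdle model log-prior at natural-scale parameters
#'
#' Multivariate Gaussian priors on `beta` (mean 0) and `gamma` (mean
#' `c(log(100), 0, ...)`, a 100 km prior baseline distance), with covariance
#' decomposed into half-Cauchy(0,1) scales and an LKJ(2) correlation;
#' zero-mean Gaussian priors on each varying intercept given its scale; and
#' half-Cauchy(0,1) priors on every scale.
#'
#' @param params list with `beta`, `gamma`, `S`, `T`, `U`, `V`, scales
#'   `sigma_S`, `sigma_T`, `sigma_U`, `sigma_V`, `sigma_e`, and optionally
#'   the covariance decompositions `tau_beta`, `L_beta`, `tau_gamma`,
#'   `L_gamma` (scale vectors and correlation Cholesky factors; defaults:
#'   unit scales, identity correlation).
#' @param eta_lkj LKJ shape for the correlation priors.
#' @return scalar log-prior; `-Inf` outside the support.
#' @export
migration_logprior <- function(params, eta_lkj = 2) {
  sc <- c(params$sigma_S, params$sigma_T, params$sigma_U, params$sigma_V,
          params$sigma_e)
  if (any(sc <= 0)) return(-Inf)
  K <- length(params$beta)
  tau_b <- if (is.null(params$tau_beta)) rep(1, K) else params$tau_beta
  tau_g <- if (is.null(params$tau_gamma)) rep(1, K) else params$tau_gamma
  if (any(c(tau_b, tau_g) <= 0)) return(-Inf)
  L_b <- if (is.null(params$L_beta)) diag(K) else params$L_beta
  L_g <- if (is.null(params$L_gamma)) diag(K) else params$L_gamma
  mvn <- function(x, mean, tau, L) {
    # x ~ N(mean, diag(tau) L L' diag(tau))
    z <- forwardsolve(L, (x - mean) / tau)
    -0.5 * sum(z^2) - sum(log(tau)) - sum(log(diag(L))) -
      0.5 * length(x) * log(2 * pi)
  }
  lkj_chol <- function(L, eta) {
    # LKJ density of the correlation matrix, expressed through its Cholesky
    K <- nrow(L)
    sum((K - seq_len(K) + 2 * eta - 2) * log(diag(L)))
  }
  lp <- mvn(params$beta, 0, tau_b, L_b) +
    mvn(params$gamma, c(log(100), rep(0, K - 1)), tau_g, L_g) +
    lkj_chol(L_b, eta_lkj) + lkj_chol(L_g, eta_lkj) +
    halfcauchy_logprior(log(c(tau_b, tau_g, sc))) -
    sum(log(c(tau_b, tau_g, sc)))   # remove the log-scale Jacobian term
  re <- function(x, s) if (is.null(x)) 0 else
    sum(stats::dnorm(x, 0, s, log = TRUE))
  lp + re(params$S, params$sigma_S) + re(params$T, params$sigma_T) +
    re(params$U, params$sigma_U) + re(params$V, params$sigma_V)
}

# ---- sampler-facing model object (unconstrained parameterization) --------

#' Assemble the migration hurdle model for fitting
#'
#' Builds the log-posterior and its analytic gradient over an unconstrained
#' parameter vector: regression coefficients are non-centred through their
#' scale/correlation prior decomposition (canonical partial correlations for
#' the LKJ factor, log scales), varying intercepts are non-centred
#' standard-normal deviates, and all scales are log-transformed.
#'
#' @param design a [build_migration_design()] object.
#' @param eta_lkj LKJ shape of the correlation priors.
#' @param backend `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation); both return identical values and gradients.
#' @param centre_birthplace use a centred parameterization for the
#'   birthplace intercepts `T` and `V` (worth trying when each birthplace is
#'   shared by very many outcomes); family intercepts are always non-centred
#'   (few outcomes per family).
#' @return object of class `kinloc_model` with elements `eval(theta)`
#'   (log-posterior, gradient and pointwise log-likelihood), `natural(theta)`
#'   (named natural-scale parameters), `init(seed)` and dimension metadata.
#' @export
migration_model <- function(design, eta_lkj = 2, backend = c("cpp", "r"),
                            centre_birthplace = FALSE) {
  backend <- match.arg(backend)
  cT <- as.integer(centre_birthplace); cV <- as.integer(centre_birthplace)
  K <- ncol(design$X); Kc <- .cpc_len(K)
  L <- length(design$family_levels); B <- length(design$place_levels)
  gr <- .mig_groups(design$outcomes)
  lens <- c(yb = Kc, ltb = K, beta = K, yg = Kc, ltg = K, gamma = K,
            zS = L, zT = B, zU = L, zV = B, ls = 5)
  off <- cumsum(c(0, lens))
  ix <- lapply(seq_along(lens), function(i) off[i] + seq_len(lens[i]))
  names(ix) <- names(lens)
  npar <- sum(lens)
  gamma_mean <- c(log(100), rep(0, K - 1))
  X <- design$X; li <- design$family; bi <- design$place
  xn <- colnames(X)
  mod <- list(kind = "migration", design = design, K = K, L = L, B = B,
              n = nrow(X), npar = npar, ix = ix, eta_lkj = eta_lkj,
              backend = backend)
  # status codes and per-outcome censoring constants for the compiled core
  stc <- integer(nrow(X)); val1 <- numeric(nrow(X)); val2 <- numeric(nrow(X))
  stc[gr$i0] <- 0L
  stc[gr$ip] <- 1L; val1[gr$ip] <- gr$logd
  stc[gr$ic] <- 2L; val1[gr$ic] <- gr$la; val2[gr$ic] <- gr$lb
  stc[gr$iu] <- 3L; val1[gr$iu] <- gr$lbu
  eval_r <- function(theta) {
    yb <- theta[ix$yb]; ltb <- theta[ix$ltb]; beta <- theta[ix$beta]
    yg <- theta[ix$yg]; ltg <- theta[ix$ltg]; gamma <- theta[ix$gamma]
    zS <- theta[ix$zS]; zT <- theta[ix$zT]
    zU <- theta[ix$zU]; zV <- theta[ix$zV]
    ls <- theta[ix$ls]
    sig <- exp(ls)
    Lb <- cpc_chol(tanh(yb), K); Lg <- cpc_chol(tanh(yg), K)
    S <- sig[1] * zS; U <- sig[3] * zU
    TT <- if (cT) zT else sig[2] * zT
    V <- if (cV) zV else sig[4] * zV
    sE <- sig[5]
    eta <- drop(X %*% beta) + S[li] + TT[bi]
    mu <- drop(X %*% gamma) + U[li] + V[bi]
    h <- .hurdle_ll(eta, mu, sE, gr)
    mb <- .mvn_centred_r(beta, 0, ltb, Lb)
    mg <- .mvn_centred_r(gamma, gamma_mean, ltg, Lg)
    lpT <- if (cT) -0.5 * sum(TT^2) / sig[2]^2 - B * ls[2] else -0.5 * sum(zT^2)
    lpV <- if (cV) -0.5 * sum(V^2) / sig[4]^2 - B * ls[4] else -0.5 * sum(zV^2)
    lp <- sum(h$ll) + mb$lp + mg$lp -
      0.5 * (sum(zS^2) + sum(zU^2)) + lpT + lpV +
      lkj_cpc_logprior(yb, K, eta_lkj) + lkj_cpc_logprior(yg, K, eta_lkj) +
      halfcauchy_logprior(c(ltb, ltg, ls))
    g <- numeric(npar)
    gbeta <- drop(crossprod(X, h$ge))
    ggamma <- drop(crossprod(X, h$gm))
    gS <- .groupsum(h$ge, li, L); gT <- .groupsum(h$ge, bi, B)
    gU <- .groupsum(h$gm, li, L); gV <- .groupsum(h$gm, bi, B)
    g[ix$beta] <- gbeta + mb$gx
    g[ix$ltb] <- mb$glt + halfcauchy_logprior_grad(ltb)
    g[ix$yb] <- cpc_chol_grad(yb, K, mb$GL) +
      lkj_cpc_logprior_grad(yb, K, eta_lkj)
    g[ix$gamma] <- ggamma + mg$gx
    g[ix$ltg] <- mg$glt + halfcauchy_logprior_grad(ltg)
    g[ix$yg] <- cpc_chol_grad(yg, K, mg$GL) +
      lkj_cpc_logprior_grad(yg, K, eta_lkj)
    g[ix$zS] <- sig[1] * gS - zS
    g[ix$zT] <- if (cT) gT - TT / sig[2]^2 else sig[2] * gT - zT
    g[ix$zU] <- sig[3] * gU - zU
    g[ix$zV] <- if (cV) gV - V / sig[4]^2 else sig[4] * gV - zV
    g[ix$ls] <- c(sig[1] * sum(zS * gS),
                  if (cT) sum(TT^2) / sig[2]^2 - B else sig[2] * sum(zT * gT),
                  sig[3] * sum(zU * gU),
                  if (cV) sum(V^2) / sig[4]^2 - B else sig[4] * sum(zV * gV),
                  h$glsE) +
      halfcauchy_logprior_grad(ls)
    list(lp = lp, grad = g, ll = h$ll)
  }
  mod$eval <- if (backend == "cpp") {
    Xt <- t(X)
    function(theta) .mig_eval_cpp(theta, Xt, li, bi, stc, val1, val2,
                                  L, B, eta_lkj, gamma_mean, cT, cV)
  } else {
    eval_r
  }
  mod$natural <- function(theta) {
    sig <- exp(theta[ix$ls])
    stats::setNames(
      c(theta[ix$beta], theta[ix$gamma], sig,
        sig[1] * theta[ix$zS],
        if (cT) theta[ix$zT] else sig[2] * theta[ix$zT],
        sig[3] * theta[ix$zU],
        if (cV) theta[ix$zV] else sig[4] * theta[ix$zV]),
      c(paste0("beta.", xn), paste0("gamma.", xn),
        c("sigma_S", "sigma_T", "sigma_U", "sigma_V", "sigma_E"),
        paste0("S.", design$family_levels), paste0("T.", design$place_levels),
        paste0("U.", design$family_levels), paste0("V.", design$place_levels)))
  }
  mod$natural_names <- names(mod$natural(numeric(npar)))
  mod$init <- function(rng_scale = 0.1) {
    th <- stats::rnorm(npar, 0, rng_scale)
    th[ix$gamma] <- th[ix$gamma] + gamma_mean
    th
  }
  class(mod) <- "kinloc_model"
  mod
}

# centred multivariate-normal coefficient block x ~ N(mean, D L L' D),
# D = diag(exp(lt)): log-density and gradients wrt x, lt and the Cholesky
# factor (the latter as a GL matrix for cpc_chol_grad)
.mvn_centred_r <- function(x, mean, lt, Lc) {
  tau <- exp(lt)
  w <- (x - mean) / tau
  z <- forwardsolve(Lc, w)
  a <- backsolve(t(Lc), z)
  GL <- a %o% z
  diag(GL) <- diag(GL) - 1 / diag(Lc)
  list(lp = -0.5 * sum(z^2) - sum(lt) - sum(log(diag(Lc))) -
         0.5 * length(x) * log(2 * pi),
       gx = -a / tau, glt = a * w - 1, GL = GL)
}

.groupsum <- function(x, idx, n) {
  out <- numeric(n)
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs))] <- rs
  out
}
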