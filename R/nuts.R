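# Gradient-based no-U-turn sampler with dual-averaging step-size adaptation
# and diagonal mass-matrix estimation during warmup.  The sampler backend is
# an adapter: `fit()` only requires a model object exposing `eval(theta)`
# returning the joint log-density and its gradient, so any asymptotically
# correct sampler for that log-density could be slotted in.

.leapfrog <- function(q, p, eps, ev, minv, fn) {
  p <- p + 0.5 * eps * ev$grad
  q <- q + eps * (minv * p)
  ev2 <- tryCatch(fn(q), error = function(e) NULL)
  if (is.null(ev2) || !is.finite(ev2$lp)) {
    return(list(q = q, p = p, ev = list(lp = -Inf, grad = 0 * q), bad = TRUE))
  }
  p <- p + 0.5 * eps * ev2$grad
  list(q = q, p = p, ev = ev2, bad = FALSE)
}

.joint <- function(ev, p, minv) ev$lp - 0.5 * sum(p^2 * minv)

# recursive tree doubling (slice-sampling no-U-turn variant)
.build_tree <- function(q, p, ev, logu, v, j, eps, joint0, minv, fn) {
  if (j == 0L) {
    st <- .leapfrog(q, p, v * eps, ev, minv, fn)
    jn <- .joint(st$ev, st$p, minv)
    div <- !is.finite(jn) || (joint0 - jn) > 1000
    n1 <- if (!div && logu <= jn) 1L else 0L
    s1 <- !div && (logu < jn + 1000)
    a <- min(1, exp(jn - joint0))
    if (!is.finite(a)) a <- 0
    return(list(qm = st$q, pm = st$p, evm = st$ev, qp = st$q, pp = st$p,
                evp = st$ev, qq = st$q, evq = st$ev, n = n1, s = s1,
                alpha = a, nalpha = 1L, div = div))
  }
  t1 <- .build_tree(q, p, ev, logu, v, j - 1L, eps, joint0, minv, fn)
  if (!t1$s) return(t1)
  if (v == -1) {
    t2 <- .build_tree(t1$qm, t1$pm, t1$evm, logu, v, j - 1L, eps, joint0,
                      minv, fn)
    t1$qm <- t2$qm; t1$pm <- t2$pm; t1$evm <- t2$evm
  } else {
    t2 <- .build_tree(t1$qp, t1$pp, t1$evp, logu, v, j - 1L, eps, joint0,
                      minv, fn)
    t1$qp <- t2$qp; t1$pp <- t2$pp; t1$evp <- t2$evp
  }
  ntot <- t1$n + t2$n
  if (t2$n > 0L && stats::runif(1) < t2$n / ntot) {
    t1$qq <- t2$qq; t1$evq <- t2$evq
  }
  dq <- t1$qp - t1$qm
  t1$s <- t2$s && sum(dq * t1$pm) >= 0 && sum(dq * t1$pp) >= 0
  t1$n <- ntot
  t1$alpha <- t1$alpha + t2$alpha
  t1$nalpha <- t1$nalpha + t2$nalpha
  t1$div <- t1$div || t2$div
  t1
}

.find_eps <- function(q, ev, minv, fn) {
  eps <- 1
  p <- stats::rnorm(length(q)) / sqrt(minv)
  j0 <- .joint(ev, p, minv)
  st <- .leapfrog(q, p, eps, ev, minv, fn)
  a <- .joint(st$ev, st$p, minv) - j0
  if (!is.finite(a)) a <- -Inf
  dir <- if (a > log(0.5)) 1 else -1
  for (k in 1:50) {
    eps <- eps * 2^dir
    st <- .leapfrog(q, p, eps, ev, minv, fn)
    a <- .joint(st$ev, st$p, minv) - j0
    if (!is.finite(a)) a <- -Inf
    if ((dir == 1 && a <= log(0.5)) || (dir == -1 && a >= log(0.5))) break
  }
  eps
}

.nuts_chain <- function(model, warmup, iter, seed, init, adapt_delta,
                        max_treedepth, progress = FALSE) {
  set.seed(seed)
  q <- if (is.null(init)) model$init() else init
  fn <- model$eval
  ev <- fn(q)
  if (!is.finite(ev$lp)) {
    stop("non-finite log-posterior at initialization; theta = ",
         paste(signif(utils::head(q, 8), 3), collapse = ", "), " ...")
  }
  d <- length(q)
  minv <- rep(1, d)
  eps <- .find_eps(q, ev, minv, fn)
  # dual averaging state
  mu_da <- log(10 * eps); Hbar <- 0; leps_bar <- 0; gam <- 0.05
  t0 <- 10; kap <- 0.75; mcount <- 0
  # mass-matrix estimation in expanding windows, with initial and terminal
  # step-size-only buffers scaled to the warmup length
  init_buf <- max(15L, round(0.15 * warmup))
  term_buf <- max(10L, round(0.10 * warmup))
  wm_starts <- integer(0)
  if (warmup > init_buf + term_buf + 20L) {
    s <- init_buf; w <- max(25L, round((warmup - init_buf - term_buf) / 3))
    while (s < warmup - term_buf) { wm_starts <- c(wm_starts, s); s <- s + w; w <- 2L * w }
    wm_ends <- c(wm_starts[-1], warmup - term_buf)
  } else wm_ends <- integer(0)
  wsum <- numeric(d); wsum2 <- numeric(d); wn <- 0
  draws <- matrix(NA_real_, iter, d)
  divergences <- 0L
  total <- warmup + iter
  for (it in seq_len(total)) {
    p0 <- stats::rnorm(d) / sqrt(minv)
    joint0 <- .joint(ev, p0, minv)
    logu <- joint0 + log(stats::runif(1))
    qm <- q; qp <- q; pm <- p0; pp <- p0; evm <- ev; evp <- ev
    n <- 1L; s <- TRUE; j <- 0L
    alpha <- 0; nalpha <- 0L; div_it <- FALSE
    while (s && j < max_treedepth) {
      v <- if (stats::runif(1) < 0.5) -1 else 1
      if (v == -1) {
        t <- .build_tree(qm, pm, evm, logu, v, j, eps, joint0, minv, fn)
        qm <- t$qm; pm <- t$pm; evm <- t$evm
      } else {
        t <- .build_tree(qp, pp, evp, logu, v, j, eps, joint0, minv, fn)
        qp <- t$qp; pp <- t$pp; evp <- t$evp
      }
      if (t$s && t$n > 0L && stats::runif(1) < min(1, t$n / n)) {
        q <- t$qq; ev <- t$evq
      }
      n <- n + t$n
      alpha <- alpha + t$alpha; nalpha <- nalpha + t$nalpha
      div_it <- div_it || t$div
      dq <- qp - qm
      s <- t$s && sum(dq * pm) >= 0 && sum(dq * pp) >= 0
      j <- j + 1L
    }
    accept <- if (nalpha > 0) alpha / nalpha else 0
    if (it <= warmup) {
      mcount <- mcount + 1
      Hbar <- (1 - 1 / (mcount + t0)) * Hbar +
        (adapt_delta - accept) / (mcount + t0)
      leps <- mu_da - sqrt(mcount) / gam * Hbar
      w_da <- mcount^(-kap)
      leps_bar <- w_da * leps + (1 - w_da) * leps_bar
      eps <- exp(leps)
      # accumulate for the mass matrix inside the current window
      if (length(wm_ends) && it > init_buf && it <= max(wm_ends)) {
        wsum <- wsum + q; wsum2 <- wsum2 + q^2; wn <- wn + 1
        if (it %in% wm_ends && wn > 10) {
          v <- (wsum2 - wsum^2 / wn) / (wn - 1)
          minv <- (wn / (wn + 5)) * v + 1e-3 * (5 / (wn + 5))
          minv <- pmax(minv, 1e-8)
          wsum[] <- 0; wsum2[] <- 0; wn <- 0
          eps <- .find_eps(q, ev, minv, fn)
          mu_da <- log(10 * eps); Hbar <- 0; leps_bar <- log(eps); mcount <- 0
        }
      }
      if (it == warmup) eps <- exp(leps_bar)
    } else {
      if (div_it) divergences <- divergences + 1L
      draws[it - warmup, ] <- q
    }
    if (progress && it %% 200 == 0) {
      message(sprintf("  iter %d/%d (eps = %.3g)", it, total, eps))
    }
  }
  list(draws = draws, divergences = divergences, eps = eps)
}

#' Fit configuration
#'
#' Defaults mirror the analysis configuration of the study the package
#' implements (4 chains, 6,500 warmup and 1,500 kept draws per chain); tests
#' and examples use much shorter chains.
#'
#' @param chains number of chains.
#' @param warmup warmup iterations per chain (discarded).
#' @param iter kept iterations per chain.
#' @param seed integer seed; chain `c` uses `seed + c`.
#' @param adapt_delta dual-averaging target acceptance statistic.
#' @param max_treedepth NUTS doubling cap.
#' @return list of class `kinloc_fit_config`.
#' @export
fit_config <- function(chains = 4L, warmup = 6500L, iter = 1500L, seed = 1L,
                       adapt_delta = 0.9, max_treedepth = 10L) {
  structure(list(chains = chains, warmup = warmup, iter = iter, seed = seed,
                 adapt_delta = adapt_delta, max_treedepth = max_treedepth),
            class = "kinloc_fit_config")
}

#' Sample the posterior of a model by NUTS
#'
#' @param model a `kinloc_model` (from [migration_model()],
#'   [residence_model()], or any object with `eval(theta)` returning
#'   `list(lp, grad)`, an `init()` function and `npar`).
#' @param config a [fit_config()].
#' @param natural report draws on the natural parameter scale (requires
#'   `model$natural`); otherwise the unconstrained vector is stored.
#' @param progress print progress messages.
#' @return object of class `kinloc_fit`: `draws` is an
#'   iterations x chains x parameters array, `diagnostics` a per-parameter
#'   table of split R-hat and effective sample sizes, `divergences` a
#'   per-chain count.  Warmup draws are never retained.
#' @export
fit <- function(model, config = fit_config(), natural = TRUE,
                progress = FALSE) {
  chains <- config$chains
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    if (progress) message(sprintf("chain %d/%d", ch, chains))
    res[[ch]] <- .nuts_chain(model, config$warmup, config$iter,
                             seed = config$seed + ch, init = NULL,
                             adapt_delta = config$adapt_delta,
                             max_treedepth = config$max_treedepth,
                             progress = progress)
  }
  use_nat <- natural && is.function(model$natural)
  pn <- if (use_nat) model$natural_names else paste0("theta.", seq_len(model$npar))
  np <- length(pn)
  draws <- array(NA_real_, c(config$iter, chains, np),
                 dimnames = list(NULL, NULL, pn))
  for (ch in seq_len(chains)) {
    m <- res[[ch]]$draws
    if (use_nat) m <- t(apply(m, 1, model$natural))
    draws[, ch, ] <- m
  }
  div <- vapply(res, `[[`, integer(1), "divergences")
  diag <- fit_diagnostics(draws)
  maxrh <- suppressWarnings(max(diag$rhat, na.rm = TRUE))
  if (is.finite(maxrh) && maxrh > 1.01) {
    warning(sprintf("max split R-hat %.3f exceeds 1.01; chains may not have mixed",
                    maxrh))
  }
  structure(list(draws = draws, diagnostics = diag, divergences = div,
                 theta_draws = do.call(rbind, lapply(res, `[[`, "draws")),
                 model = model, config = config),
            class = "kinloc_fit")
}

#' @export
print.kinloc_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("kinloc_fit: %d chains x %d draws, %d parameters\n",
              d[2], d[1], d[3]))
  cat(sprintf("max split R-hat %.4f, divergences %s\n",
              suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
              paste(x$divergences, collapse = "/")))
  invisible(x)
}

# ---- convergence diagnostics --------------------------------------------

.split_chains <- function(m) {
  # m: iterations x chains -> halved chains side by side
  n <- nrow(m) %/% 2L
  cbind(m[seq_len(n), , drop = FALSE],
        m[n + seq_len(n), , drop = FALSE])
}

#' Split R-hat of one parameter
#' @param m matrix iterations x chains.
#' @return potential-scale-reduction statistic (>= 1 up to floating error).
#' @export
split_rhat <- function(m) {
  m <- .split_chains(as.matrix(m))
  if (stats::var(as.numeric(m)) == 0) return(NA_real_)
  n <- nrow(m)
  mu <- colMeans(m)
  B <- n * stats::var(mu)
  W <- mean(apply(m, 2, stats::var))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via Geyer's initial monotone positive sequence
.ess_mat <- function(m) {
  m <- .split_chains(as.matrix(m))
  n <- nrow(m); ch <- ncol(m)
  if (n < 4L) return(NA_real_)
  W <- mean(apply(m, 2, stats::var))
  if (W == 0 || !is.finite(W)) return(NA_real_)
  mu <- colMeans(m)
  B <- if (ch > 1) n * stats::var(mu) else 0
  varplus <- W * (n - 1) / n + B / n
  acov <- vapply(seq_len(ch), function(j) {
    drop(stats::acf(m[, j], lag.max = n - 1, type = "covariance",
                    plot = FALSE)$acf)
  }, numeric(n))
  rho <- 1 - (W - rowMeans(acov)) / varplus  # rho[1] is lag 0
  rho[1] <- 1
  # paired sums (lag 2k, 2k+1), kept while positive, then made monotone
  P <- numeric(0)
  k <- 0L
  while (2L * k + 2L <= n) {
    s <- rho[2L * k + 1L] + rho[2L * k + 2L]
    if (s <= 0) break
    P <- c(P, s)
    k <- k + 1L
  }
  if (length(P) > 1L) P <- cummin(P)
  tau <- max(-1 + 2 * sum(P), 1 / n)
  min(ch * n / tau, ch * n * log10(ch * n))
}

#' Bulk effective sample size (rank-normalized)
#' @param m matrix iterations x chains.
#' @return effective sample size estimate.
#' @export
ess_bulk <- function(m) {
  m <- as.matrix(m)
  z <- stats::qnorm((rank(m) - 0.5) / length(m))
  .ess_mat(matrix(z, nrow(m), ncol(m)))
}

#' Tail effective sample size (minimum over the 5% and 95% quantile
#' indicator sequences)
#' @param m matrix iterations x chains.
#' @return effective sample size estimate.
#' @export
ess_tail <- function(m) {
  m <- as.matrix(m)
  q <- stats::quantile(m, c(0.05, 0.95), names = FALSE)
  e1 <- .ess_mat(matrix(as.numeric(m <= q[1]), nrow(m), ncol(m)))
  e2 <- .ess_mat(matrix(as.numeric(m >= q[2]), nrow(m), ncol(m)))
  if (is.na(e1) && is.na(e2)) return(NA_real_)
  min(e1, e2, na.rm = TRUE)
}

#' Per-parameter convergence diagnostics of a draws array
#' @param draws iterations x chains x parameters array.
#' @return data frame with `parameter`, `rhat`, `ess_bulk`, `ess_tail`.
#' @export
fit_diagnostics <- function(draws) {
  pn <- dimnames(draws)[[3]]
  out <- data.frame(parameter = pn, rhat = NA_real_, ess_bulk = NA_real_,
                    ess_tail = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(pn)) {
    m <- draws[, , k, drop = TRUE]
    m <- matrix(m, dim(draws)[1], dim(draws)[2])
    z <- stats::qnorm((rank(m) - 0.5) / length(m))
    out$rhat[k] <- split_rhat(matrix(z, nrow(m), ncol(m)))
    out$ess_bulk[k] <- ess_bulk(m)
    out$ess_tail[k] <- ess_tail(m)
  }
  out
}

#' Posterior summary table
#'
#' @param object a `kinloc_fit` or a draws array.
#' @param pars optional regular expression selecting parameters.
#' @return data frame with posterior mean, sd, central 50% and 90%
#'   intervals, split R-hat, effective sample sizes and a
#'   `well_supported` flag (TRUE when the central 90% interval excludes 0).
#' @export
summarize_draws <- function(object, pars = NULL) {
  draws <- if (inherits(object, "kinloc_fit")) object$draws else object
  pn <- dimnames(draws)[[3]]
  keep <- if (is.null(pars)) seq_along(pn) else grep(pars, pn)
  out <- lapply(keep, function(k) {
    m <- matrix(draws[, , k], dim(draws)[1], dim(draws)[2])
    x <- as.numeric(m)
    qs <- stats::quantile(x, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
    data.frame(parameter = pn[k], mean = mean(x), sd = stats::sd(x),
               q5 = qs[1], q25 = qs[2], q75 = qs[3], q95 = qs[4],
               rhat = {
                 z <- stats::qnorm((rank(m) - 0.5) / length(m))
                 split_rhat(matrix(z, nrow(m), ncol(m)))
               },
               ess_bulk = ess_bulk(m), ess_tail = ess_tail(m),
               well_supported = qs[1] > 0 | qs[4] < 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pointwise log-likelihood matrix of a fit
#'
#' Re-evaluates the model's pointwise log-likelihood at every kept draw,
#' producing the draws x observations matrix consumed by PSIS-LOO.
#' @param fit a `kinloc_fit`.
#' @return matrix (total draws x observations).
#' @export
pointwise_loglik <- function(fit) {
  model <- fit$model
  th <- fit$theta_draws
  out <- matrix(NA_real_, nrow(th), model$n)
  for (s in seq_len(nrow(th))) out[s, ] <- model$eval(th[s, ])$ll
  out
}
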