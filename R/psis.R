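# Pareto-smoothed importance sampling and approximate leave-one-out
# cross-validation (PSIS-LOO) for the fitted models.

#' Fit a generalized Pareto distribution to sample tails
#'
#' Profile-likelihood estimator of the shape `k` and scale `sigma` with a
#' weakly informative prior pulling `k` towards 1/2 (the standard PSIS
#' practice).  Parameterization: `1 - (1 + k x / sigma)^(-1/k)` on `x > 0`.
#'
#' @param x positive exceedances.
#' @param wip apply the weakly informative shape regularization.
#' @return list with `k` (regularized), `sigma` and `k_raw`.
#' @export
gpd_fit <- function(x, wip = TRUE) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar) + 1 / x[n]
  # profile log-likelihood over b, with shape k(b) profiled out
  ks <- vapply(bs, function(b) mean(log1p(-b * x)), numeric(1))
  Lk <- n * (log(-bs / ks) - ks - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(Lk - Lk[j])), numeric(1))
  b <- sum(bs * w)
  k_raw <- mean(log1p(-b * x))
  sigma <- -k_raw / b
  k_reg <- if (wip) (n * k_raw + 10 * 0.5) / (n + 10) else k_raw
  list(k = k_reg, sigma = sigma, k_raw = k_raw)
}

.qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * expm1(-k * log1p(-p)) / k
}

#' Pareto-smooth a vector of importance log-ratios
#'
#' The largest `M = ceiling(min(0.2 S, 3 sqrt(S)))` ratios are replaced by
#' expected order statistics of a generalized Pareto distribution fitted to
#' the tail, then all ratios are truncated at the raw maximum and
#' normalized.
#'
#' @param log_ratios numeric vector of length S (posterior draws).
#' @return list with normalized `log_weights` (summing to 1 on the
#'   probability scale) and the Pareto shape diagnostic `k` (`-Inf` flags a
#'   degenerate, constant-ratio case).
#' @export
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  lr <- log_ratios - max(log_ratios)
  if (stats::sd(lr) == 0) {
    return(list(log_weights = rep(-log(S), S), k = -Inf))
  }
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  ord <- order(lr)
  tail_ids <- ord[(S - M + 1L):S]
  cut <- lr[ord[S - M]]
  exc <- exp(lr[tail_ids]) - exp(cut)
  k <- NA_real_
  lw <- lr
  if (max(exc) > 0) {
    fitg <- gpd_fit(exc[exc > 0])
    k <- fitg$k
    if (is.finite(k)) {
      qq <- .qgpd((seq_len(M) - 0.5) / M, fitg$k, fitg$sigma)
      smoothed <- log(exp(cut) + qq)
      # preserve the original ordering of the tail
      lw[tail_ids[order(exc)]] <- sort(smoothed)
      lw <- pmin(lw, 0)  # truncate at the raw maximum (= 0 after shift)
    }
  }
  lw <- lw - .logsumexp(lw)
  list(log_weights = lw, k = k)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' PSIS-LOO expected log predictive density
#'
#' @param loglik matrix of pointwise log-likelihood values
#'   (draws x observations).
#' @return object of class `kinloc_loo`: `elpd`, its `se`, per-observation
#'   `pointwise` contributions and Pareto `k` diagnostics.
#' @export
loo_elpd <- function(loglik) {
  n <- ncol(loglik)
  pw <- numeric(n); ks <- numeric(n)
  for (i in seq_len(n)) {
    ps <- psis_smooth(-loglik[, i])
    pw[i] <- .logsumexp(ps$log_weights + loglik[, i])
    ks[i] <- ps$k
  }
  structure(list(elpd = sum(pw), se = sqrt(n * stats::var(pw)),
                 pointwise = pw, k = ks),
            class = "kinloc_loo")
}

#' @export
print.kinloc_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO elpd %.2f (SE %.2f); %d/%d Pareto k > 0.7\n",
              x$elpd, x$se, sum(is.finite(x$k) & x$k > 0.7), length(x$k)))
  invisible(x)
}

#' Compare models by PSIS-LOO
#'
#' @param ... named pointwise log-likelihood matrices (draws x observations,
#'   same observations in the same order for every model), or `kinloc_loo`
#'   objects.
#' @return data frame ranked by elpd, with pairwise differences to the best
#'   model and the standard error of each difference (computed from the
#'   paired per-observation contributions).
#' @export
compare_models <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1L && is.list(inputs[[1]]) && is.null(dim(inputs[[1]])) &&
      !inherits(inputs[[1]], "kinloc_loo")) {
    inputs <- inputs[[1]]
  }
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    names(inputs) <- paste0("model", seq_along(inputs))
  }
  loos <- lapply(inputs, function(x) {
    if (inherits(x, "kinloc_loo")) x else loo_elpd(x)
  })
  ns <- vapply(loos, function(l) length(l$pointwise), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("models must share the same observations; pointwise lengths differ: ",
         paste(ns, collapse = ", "))
  }
  elpds <- vapply(loos, `[[`, numeric(1), "elpd")
  best <- which.max(elpds)
  out <- data.frame(
    model = names(loos),
    elpd = elpds,
    se = vapply(loos, `[[`, numeric(1), "se"),
    elpd_diff = elpds - elpds[best],
    se_diff = vapply(seq_along(loos), function(i) {
      if (i == best) return(0)
      d <- loos[[i]]$pointwise - loos[[best]]$pointwise
      sqrt(length(d) * stats::var(d))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  out[order(-out$elpd), ]
}
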