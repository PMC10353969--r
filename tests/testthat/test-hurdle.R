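test_that("hurdle log-density has its closed-form special cases", {
  # logistic(0) = 1/2: a non-migration at even odds
  expect_equal(hurdle_logdensity("observed", d = 0, eta = 0, mu = 1,
                                 sigma_e = 1), log(0.5))
  # an interval covering the whole support leaves just the migration odds
  wide <- hurdle_logdensity("interval_censored", d_min = 1e-12, d_max = 1e12,
                            eta = 0.7, mu = log(20), sigma_e = 1)
  expect_equal(wide, plogis(0.7, log.p = TRUE), tolerance = 1e-10)
  # latent-status censoring limits: to (1 - pi) as d_max -> 0+, to 1 as -> Inf
  eta <- 0.3
  lo <- hurdle_logdensity("status_unknown_censored", d_max = 1e-10, eta = eta,
                          mu = log(50), sigma_e = 1)
  expect_equal(exp(lo), 1 - plogis(eta), tolerance = 1e-8)
  hi <- hurdle_logdensity("status_unknown_censored", d_max = 1e10, eta = eta,
                          mu = log(50), sigma_e = 1)
  expect_equal(exp(hi), 1, tolerance = 1e-8)
  expect_error(hurdle_logdensity("interval_censored", d_min = 5, d_max = 5,
                                 eta = 0, mu = 0, sigma_e = 1), "d_min")
  expect_error(hurdle_logdensity("observed", d = 1, eta = 0, mu = 0,
                                 sigma_e = -1), "positive")
})

test_that("censored densities match adaptive quadrature of the lognormal", {
  q <- hurdle_logdensity("interval_censored", d_min = 5, d_max = 50,
                         eta = 0.4, mu = log(20), sigma_e = 1)
  pi1 <- plogis(0.4)
  oracle <- pi1 * integrate(function(d) dlnorm(d, log(20), 1), 5, 50,
                            rel.tol = 1e-12)$value
  expect_equal(exp(q), oracle, tolerance = 1e-8)
})

test_that("probability-scale additivity over adjacent censoring intervals", {
  set.seed(404)
  for (rep in 1:20) {
    mu <- rnorm(1, log(40), 1); s <- runif(1, 0.4, 2); eta <- rnorm(1)
    abc <- sort(exp(rnorm(3, mu, 2)))
    p12 <- exp(hurdle_logdensity("interval_censored", d_min = abc[1],
                                 d_max = abc[2], eta = eta, mu = mu,
                                 sigma_e = s)) +
      exp(hurdle_logdensity("interval_censored", d_min = abc[2],
                            d_max = abc[3], eta = eta, mu = mu, sigma_e = s))
    p13 <- exp(hurdle_logdensity("interval_censored", d_min = abc[1],
                                 d_max = abc[3], eta = eta, mu = mu,
                                 sigma_e = s))
    expect_equal(p12, p13, tolerance = 1e-10)
  }
})

test_that("the grouped likelihood equals per-outcome hurdle densities", {
  st <- tiny_study(seed = 32, nf = 10, np = 10)
  des <- build_migration_design(st$outcomes, byr_center = 1957)
  K <- ncol(des$X)
  set.seed(405)
  params <- list(beta = rnorm(K, 0, 0.5), gamma = c(log(50), rnorm(K - 1, 0, 0.3)),
                 S = rnorm(length(des$family_levels), 0, 0.5),
                 T = rnorm(length(des$place_levels), 0, 0.5),
                 U = rnorm(length(des$family_levels), 0, 0.3),
                 V = rnorm(length(des$place_levels), 0, 0.3),
                 sigma_e = 0.9)
  ll <- migration_loglik(params, des)
  expect_equal(ll$total, sum(ll$pointwise))
  o <- des$outcomes
  eta <- drop(des$X %*% params$beta) + params$S[des$family] + params$T[des$place]
  mu <- drop(des$X %*% params$gamma) + params$U[des$family] + params$V[des$place]
  oracle <- vapply(seq_len(nrow(o)), function(i) {
    hurdle_logdensity(o$status[i], d = o$d[i], d_min = o$d_min[i],
                      d_max = o$d_max[i], eta = eta[i], mu = mu[i],
                      sigma_e = params$sigma_e)
  }, numeric(1))
  expect_equal(ll$pointwise, oracle, tolerance = 1e-12)
})

test_that("the hurdle log-prior is unimodal where it should be", {
  K <- 9
  base <- list(beta = rep(0, K), gamma = c(log(100), rep(0, K - 1)),
               S = rep(0, 4), T = rep(0, 5), U = rep(0, 4), V = rep(0, 5),
               sigma_S = 1, sigma_T = 1, sigma_U = 1, sigma_V = 1, sigma_e = 1)
  lp0 <- migration_logprior(base)
  expect_true(is.finite(lp0))
  # shrinking any family intercept towards zero raises the prior
  p2 <- base; p2$S[2] <- 0.8
  p3 <- base; p3$S[2] <- 0.4
  expect_lt(migration_logprior(p2), migration_logprior(p3))
  expect_lt(migration_logprior(p3), lp0)
  # the gamma intercept prior peaks at the 100 km baseline
  p4 <- base; p4$gamma[1] <- log(100) + 0.5
  expect_lt(migration_logprior(p4), lp0)
  p5 <- base; p5$gamma[1] <- log(100) - 0.5
  expect_lt(migration_logprior(p5), lp0)
  # out-of-support scales are rejected
  p6 <- base; p6$sigma_T <- -1
  expect_identical(migration_logprior(p6), -Inf)
})

test_that("the half-Cauchy scale prior has its closed-form value at 1", {
  # density of a half-Cauchy(0,1) at sigma = 1 is 2/(pi*(1+1)) = 1/pi
  expect_equal(kinloc:::halfcauchy_logprior(0), log(2 / pi) - log(2))
})

test_that("ancestry covariates are symmetric, floored log ratios", {
  expect_equal(unname(ancestry_covariates(rbind(c(1, 1, 1) / 3))[1, ]), c(0, 0))
  expect_equal(unname(ancestry_covariates(rbind(c(0.8, 0.1, 0.1)))[1, ]),
               c(log(8), 0))
  degen <- ancestry_covariates(rbind(c(1, 0, 0)), eps = 0.001)
  expect_true(all(is.finite(degen)))
  expect_error(ancestry_covariates(rbind(c(-0.1, 0.6, 0.5))), "nonnegative")
  expect_error(ancestry_covariates(rbind(c(0.5, 0.1, 0.1))), "sum to 1")
  raw <- ancestry_covariates(rbind(c(0.8, 0.1, 0.1)), log = FALSE)
  expect_equal(unname(raw[1, ]), c(8, 1))
})

test_that("design matrices have the documented columns and indices", {
  st <- tiny_study(seed = 33, nf = 12, np = 10)
  des <- build_migration_design(st$outcomes)
  expect_equal(ncol(des$X), 9)
  expect_true(qr(des$X)$rank == 9)
  expect_false(any(st$outcomes$status == "missing" &
                     rownames(st$outcomes) %in% rownames(des$outcomes)))
  expect_equal(sort(unique(des$family)), seq_along(des$family_levels))
  expect_equal(sort(unique(des$place)), seq_along(des$place_levels))
  # settlement variant appends town/farm/unknown dummies (city reference)
  dss <- build_migration_design(st$outcomes, variant = "settlement_size")
  expect_equal(ncol(dss$X), 12)
  unk <- dss$outcomes$mover_settlement == "unknown"
  expect_equal(unname(dss$X[unk, "settlement_unknown"]), rep(1, sum(unk)))
  expect_equal(unname(dss$X[unk, "settlement_town"]), rep(0, sum(unk)))
  # ancestry variant needs the covariate table
  expect_error(build_migration_design(st$outcomes, variant = "ancestry"),
               "ancestry")
  anc <- simulate_ancestry(st$sim, st$cfg)
  dan <- build_migration_design(st$outcomes, variant = "ancestry",
                                ancestry = anc)
  expect_equal(ncol(dan$X), 11)
  # outcomes in the same family share a family index
  fidx <- split(des$family, des$outcomes$family_id)
  expect_true(all(vapply(fidx, function(v) length(unique(v)) == 1, logical(1))))
})
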