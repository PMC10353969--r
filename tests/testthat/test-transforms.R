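test_that("the CPC transform yields valid correlation Cholesky factors", {
  set.seed(411)
  for (K in c(2, 4, 9)) {
    y <- rnorm(K * (K - 1) / 2, 0, 0.8)
    L <- kinloc:::cpc_chol(tanh(y), K)
    R <- L %*% t(L)
    expect_equal(diag(R), rep(1, K))               # unit diagonal
    expect_true(all(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 0))
    expect_true(all(L[upper.tri(L)] == 0))
  }
})

test_that("LKJ draws concentrate around the identity for larger shape", {
  set.seed(412)
  off <- function(eta) {
    mean(replicate(400, {
      L <- kinloc:::rlkj_chol(3, eta)
      R <- L %*% t(L)
      abs(R[2, 1])
    }))
  }
  expect_lt(off(10), off(1))
  # and are centred: mean off-diagonal near zero
  m <- mean(replicate(400, { L <- kinloc:::rlkj_chol(3, 2); (L %*% t(L))[3, 1] }))
  expect_lt(abs(m), 0.1)
})

test_that("prior transform gradients match finite differences", {
  set.seed(413)
  K <- 5
  y <- rnorm(K * (K - 1) / 2, 0, 0.6)
  g <- kinloc:::lkj_cpc_logprior_grad(y, K, 2)
  h <- 1e-6
  fd <- vapply(seq_along(y), function(i) {
    yp <- y; ym <- y; yp[i] <- yp[i] + h; ym[i] <- ym[i] - h
    (kinloc:::lkj_cpc_logprior(yp, K, 2) -
       kinloc:::lkj_cpc_logprior(ym, K, 2)) / (2 * h)
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-6)
  ls <- rnorm(4)
  ghc <- kinloc:::halfcauchy_logprior_grad(ls)
  fdhc <- vapply(seq_along(ls), function(i) {
    lp <- ls; lm <- ls; lp[i] <- lp[i] + h; lm[i] <- lm[i] - h
    (kinloc:::halfcauchy_logprior(lp) - kinloc:::halfcauchy_logprior(lm)) / (2 * h)
  }, numeric(1))
  expect_equal(ghc, fdhc, tolerance = 1e-6)
})

test_that("compiled and reference model backends agree exactly", {
  st <- tiny_study(seed = 34, nf = 12, np = 10)
  des <- build_migration_design(st$outcomes, byr_center = 1957)
  for (cb in c(TRUE, FALSE)) {
    mr <- migration_model(des, backend = "r", centre_birthplace = cb)
    mc <- migration_model(des, backend = "cpp", centre_birthplace = cb)
    set.seed(414)
    for (rep in 1:3) {
      th <- mr$init() + rnorm(mr$npar, 0, 0.3)
      a <- mr$eval(th); b <- mc$eval(th)
      expect_equal(a$lp, b$lp, tolerance = 1e-10)
      expect_equal(a$grad, b$grad, tolerance = 1e-8)
      expect_equal(a$ll, b$ll, tolerance = 1e-10)
    }
  }
  cfgr <- st$cfg
  ro <- simulate_residence_outcomes(st$sim, cfgr, st$gazetteer)
  rdes <- build_residence_design(ro$outcomes, byr_center = 1957)
  rr <- residence_model(rdes, backend = "r")
  rc <- residence_model(rdes, backend = "cpp")
  for (rep in 1:3) {
    th <- rr$init() + rnorm(rr$npar, 0, 0.3)
    a <- rr$eval(th); b <- rc$eval(th)
    expect_equal(a$lp, b$lp, tolerance = 1e-10)
    expect_equal(a$grad, b$grad, tolerance = 1e-8)
  }
})
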