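gauss_model <- function(Q) {
  d <- nrow(Q)
  list(npar = d, init = function() stats::rnorm(d, 0, 0.5),
       eval = function(th) list(lp = -0.5 * drop(th %*% Q %*% th),
                                grad = -drop(Q %*% th), ll = 0))
}

test_that("the sampler reproduces a standard normal posterior", {
  mod <- gauss_model(diag(5))
  ft <- fit(mod, fit_config(chains = 2, warmup = 300, iter = 800, seed = 3),
            natural = FALSE)
  expect_equal(dim(ft$draws), c(800, 2, 5))
  for (k in 1:5) {
    x <- as.numeric(ft$draws[, , k])
    ess <- ess_bulk(matrix(ft$draws[, , k], 800, 2))
    expect_lt(abs(mean(x)), 3 / sqrt(ess))
    expect_lt(abs(var(x) - 1), 0.1)
  }
})

test_that("a correlated Gaussian posterior is recovered, reproducibly", {
  rho <- 0.7
  Q <- solve(matrix(c(1, rho, rho, 1), 2))
  mod <- gauss_model(Q)
  cfg <- fit_config(chains = 2, warmup = 300, iter = 700, seed = 11)
  ft <- fit(mod, cfg, natural = FALSE)
  x <- as.numeric(ft$draws[, , 1]); y <- as.numeric(ft$draws[, , 2])
  expect_lt(abs(cor(x, y) - rho), 0.05)
  expect_lt(abs(var(x) - 1), 0.12)
  ft2 <- fit(mod, cfg, natural = FALSE)
  expect_identical(ft$draws, ft2$draws)   # seeded determinism
  expect_true(all(ft$diagnostics$rhat < 1.01, na.rm = TRUE))
})

test_that("non-finite initialization is reported with a parameter dump", {
  bad <- list(npar = 3, init = function() rep(0, 3),
              eval = function(th) list(lp = NaN, grad = rep(0, 3), ll = 0))
  expect_error(fit(bad, fit_config(chains = 1, warmup = 10, iter = 10)),
               "non-finite log-posterior at initialization")
})

test_that("poor mixing triggers an R-hat warning, not a failure", {
  # two far-apart modes that single chains cannot cross
  bimodal <- list(
    npar = 1, init = function() stats::rnorm(1, 0, 0.1),
    eval = function(th) {
      d <- th[1]
      lp <- log(0.5 * exp(-0.5 * (d - 30)^2) + 0.5 * exp(-0.5 * (d + 30)^2) +
                  1e-300)
      g <- 0.5 * (-(d - 30) * exp(-0.5 * (d - 30)^2) -
                    (d + 30) * exp(-0.5 * (d + 30)^2))
      list(lp = lp, grad = g / exp(lp), ll = 0)
    })
  expect_warning(fit(bimodal, fit_config(chains = 4, warmup = 100, iter = 100,
                                         seed = 2)),
                 "R-hat")
})

test_that("marginal cell effects equal the brute-force mixture", {
  st <- tiny_study(seed = 35, nf = 8, np = 8)
  des <- build_migration_design(st$outcomes, byr_center = 1957)
  mod <- migration_model(des)
  ft <- suppressWarnings(fit(mod, fit_config(chains = 2, warmup = 60,
                                             iter = 40, seed = 5)))
  mg <- marginalize_birthplace_effects(ft)
  expect_true(all(c("region", "generation", "sex", "odds", "distance_km")
                  %in% names(mg)))
  # brute-force oracle for one cell and all draws
  o <- des$outcomes
  cl <- mg[1, c("region", "generation", "sex")]
  sel <- o$region == cl$region & o$mover_generation == cl$generation &
    o$mover_sex == cl$sex
  tb <- table(o$anchor_place[sel]); w <- as.numeric(tb) / sum(tb)
  x <- kinloc:::.mig_cell_x(des, cl$region, cl$generation, cl$sex)
  dr <- ft$draws
  S <- dim(dr)[1] * dim(dr)[2]
  beta <- matrix(dr[, , grep("^beta\\.", dimnames(dr)[[3]])], S)
  oracle <- numeric(S)
  for (s in seq_len(S)) {
    acc <- 0
    for (j in seq_along(w)) {
      tb_j <- dr[, , paste0("T.", names(tb)[j])][s]
      acc <- acc + w[j] * exp(sum(x * beta[s, ]) + tb_j)
    }
    oracle[s] <- acc
  }
  got <- mg[mg$region == cl$region & mg$generation == cl$generation &
              mg$sex == cl$sex, "odds"]
  expect_equal(got, oracle, tolerance = 1e-10)
  # degenerate mixture: a single birthplace with weight 1
  key <- paste(cl$region, cl$generation, cl$sex, sep = ".")
  wts <- stats::setNames(list(stats::setNames(1, names(tb)[1])), key)
  mg1 <- suppressWarnings(marginalize_birthplace_effects(ft, weights = wts))
  one <- mg1[mg1$region == cl$region & mg1$generation == cl$generation &
               mg1$sex == cl$sex, "odds"]
  oracle1 <- exp(beta %*% x + dr[, , paste0("T.", names(tb)[1])][seq_len(S)])
  expect_equal(one, as.numeric(oracle1), tolerance = 1e-10)
})
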