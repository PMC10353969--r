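test_that("generation is a deterministic function of the configuration", {
  cfg <- sim_config(seed = 51, n_families_per_region = 8, n_places_per_region = 8)
  a <- simulate_gazetteer(cfg); b <- simulate_gazetteer(cfg)
  expect_identical(a, b)
  fa <- simulate_families(cfg, a$gazetteer, a$polygons)
  fb <- simulate_families(cfg, b$gazetteer, b$polygons)
  expect_identical(fa, fb)
  ra <- simulate_residence_outcomes(fa, cfg, a$gazetteer)
  rb <- simulate_residence_outcomes(fb, cfg, b$gazetteer)
  expect_identical(ra, rb)
})

test_that("every simulated birthplace lies inside its region polygon", {
  cfg <- sim_config(seed = 52, n_places_per_region = 25)
  gz <- simulate_gazetteer(cfg)
  for (r in names(gz$polygons)) {
    g <- gz$gazetteer[gz$gazetteer$region == r, ]
    ring <- gz$polygons[[r]]
    ring <- rbind(ring, ring[1, ])
    inside <- mgcv::in.out(cbind(ring$lon, ring$lat), cbind(g$lon, g$lat))
    expect_true(all(inside))
  }
  # overlapping regions are rejected
  bad <- sim_config(regions = list(A = list(center = c(0, 0), half = 1),
                                   B = list(center = c(0.5, 0.5), half = 1)))
  expect_error(simulate_gazetteer(bad), "overlap")
})

test_that("degenerate migration truths produce degenerate pedigrees", {
  cfg0 <- sim_config(seed = 53, n_families_per_region = 15,
                     n_places_per_region = 10)
  cfg0$beta["intercept"] <- -30   # nobody migrates
  gz <- simulate_gazetteer(cfg0)
  sim0 <- simulate_families(cfg0, gz$gazetteer, gz$polygons)
  expect_true(all(!sim0$truth$dyads$migrated))
  expect_true(all(sim0$truth$dyads$d_true == 0))
  ro0 <- build_residence_outcomes(sim0$persons)
  expect_true(all(ro0$type == "equilocal"))
  cfg1 <- cfg0; cfg1$beta["intercept"] <- 30   # everybody migrates
  sim1 <- simulate_families(cfg1, gz$gazetteer, gz$polygons)
  expect_true(all(sim1$truth$dyads$migrated))
  expect_true(all(sim1$truth$dyads$d_true > 0))
  ro1 <- build_residence_outcomes(sim1$persons)
  expect_false(any(ro1$type == "equilocal"))
})

test_that("observed migrant fraction matches the model-implied marginal", {
  cfg <- sim_config(seed = 54, n_families_per_region = 100,
                    n_places_per_region = 20)
  gz <- simulate_gazetteer(cfg)
  sim <- simulate_families(cfg, gz$gazetteer, gz$polygons)
  obs_frac <- mean(sim$truth$dyads$migrated)
  # Monte-Carlo marginal probability from the truth parameters
  set.seed(999)
  nmc <- 40000
  byr <- (round(rnorm(nmc, cfg$median_birth_year, cfg$birth_year_sd)) -
            cfg$median_birth_year) / 10
  sexm <- rbinom(nmc, 1, 0.5)             # movers are male half the time
  genp <- rbinom(nmc, 1, 1 / 3)           # 2 of 6 dyads are parental
  regR <- rbinom(nmc, 1, 0.5)
  eta <- cfg$beta["intercept"] + cfg$beta["birth_year"] * byr +
    cfg$beta["sex_male"] * sexm + cfg$beta["generation_parent"] * genp +
    cfg$beta["region_Richtersveld"] * regR +
    rnorm(nmc, 0, cfg$sigma_S) + rnorm(nmc, 0, cfg$sigma_T)
  pmc <- mean(plogis(eta))
  n <- nrow(sim$truth$dyads)
  expect_lt(abs(obs_frac - pmc), 3 * sqrt(pmc * (1 - pmc) / n) + 0.01)
})

test_that("degradation follows its rates and never touches the truth", {
  cfg <- sim_config(seed = 55, n_families_per_region = 40,
                    n_places_per_region = 10)
  gz <- simulate_gazetteer(cfg)
  sim <- simulate_families(cfg, gz$gazetteer, gz$polygons)
  cfg0 <- cfg; cfg0$censor_rate <- 0; cfg0$missing_rate <- 0
  un <- degrade(sim, cfg0)
  expect_identical(un$persons, sim$persons)
  expect_identical(un$truth, sim$truth)
  cfg1 <- cfg; cfg1$censor_rate <- 1; cfg1$missing_rate <- 0
  all_cens <- degrade(sim, cfg1)
  gp <- grepl("grand", all_cens$persons$role)
  expect_true(all(all_cens$persons$bk[gp] == "region_only"))
  expect_identical(all_cens$truth, sim$truth)
  # probands are never degraded
  deg <- degrade(sim, cfg)
  expect_true(all(deg$persons$bk[deg$persons$role == "proband"] == "exact"))
})

test_that("grandparent missingness can depend on the parent's migration", {
  cfg <- sim_config(seed = 56, n_families_per_region = 250,
                    n_places_per_region = 10, missing_rate = 0.2,
                    missing_dependence_or = 4)
  gz <- simulate_gazetteer(cfg)
  sim <- simulate_families(cfg, gz$gazetteer, gz$polygons)
  deg <- degrade(sim, cfg)
  pro <- sim$persons[sim$persons$role == "proband", ]
  tab <- matrix(0, 2, 2)
  for (side in c("mother", "father")) {
    par <- sim$persons[sim$persons$role == side, ]
    moved <- par$place_id[match(pro$family_id, par$family_id)] != pro$place_id
    gp_roles <- if (side == "mother") {
      c("maternal_grandmother", "maternal_grandfather")
    } else {
      c("paternal_grandmother", "paternal_grandfather")
    }
    for (gr in gp_roles) {
      gp <- deg$persons[deg$persons$role == gr, ]
      miss <- gp$bk[match(pro$family_id, gp$family_id)] == "unknown"
      tab <- tab + table(factor(moved, c(FALSE, TRUE)),
                         factor(miss, c(FALSE, TRUE)))
    }
  }
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_gt(or, 1)
})

test_that("type-first residence simulation is classifier-consistent", {
  cfg <- sim_config(seed = 57, n_families_per_region = 30,
                    n_places_per_region = 10)
  gz <- simulate_gazetteer(cfg)
  sim <- simulate_families(cfg, gz$gazetteer, gz$polygons)
  ro <- simulate_residence_outcomes(sim, cfg, gz$gazetteer)
  got <- classify_residence(ro$outcomes$child_place, ro$outcomes$female_place,
                            ro$outcomes$male_place)
  expect_identical(got, ro$outcomes$type)
  # all-equilocal truth
  cfg0 <- cfg
  cfg0$delta[, ] <- 0; cfg0$delta["intercept", ] <- -30
  cfg0$sigma_W <- c(0, 0, 0) + 1e-8
  ro0 <- simulate_residence_outcomes(sim, cfg0, gz$gazetteer)
  expect_true(all(ro0$outcomes$type == "equilocal"))
})

test_that("dominant matrilocal odds reproduce the softmax frequency", {
  cfg <- sim_config(seed = 58, n_families_per_region = 170,
                    n_places_per_region = 10)
  cfg$delta[, ] <- 0
  cfg$delta["intercept", "matrilocal"] <- 2
  cfg$sigma_W <- c(0, 0, 0) + 1e-8
  gz <- simulate_gazetteer(cfg)
  sim <- simulate_families(cfg, gz$gazetteer, gz$polygons)
  ro <- simulate_residence_outcomes(sim, cfg, gz$gazetteer)
  share <- mean(ro$outcomes$type == "matrilocal")
  p <- exp(2) / (3 + exp(2))
  n <- nrow(ro$outcomes)
  expect_lt(abs(share - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("dyad-level simulation carries settlement effects", {
  cfg <- sim_config(seed = 59, n_families_per_region = 120,
                    n_places_per_region = 12,
                    beta_settlement = c(town = 0, farm = -3, unknown = 0))
  gz <- simulate_gazetteer(cfg)
  dy <- simulate_dyads(cfg, gz$gazetteer)
  frac <- tapply(dy$outcomes$migrated == "yes", dy$outcomes$mover_settlement,
                 mean)
  expect_lt(frac[["farm"]], frac[["town"]] - 0.1)
})
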