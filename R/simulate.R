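# Synthetic study generator: gazetteers and region polygons, three-generation
# families whose six migration dyads are exact draws from the hurdle model,
# multi-logit-faithful residence outcomes, ancestry profiles, and the
# observation process (region-only censoring and missingness).

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: two disjoint study
#' regions, ~60 birthplaces, 300 families, proband birth years centred on
#' 1957, roughly half of complete-case movers migrating with median
#' distances of tens of kilometres, and a missingness/censoring layer
#' mirroring incomplete informant knowledge of grandparental birthplaces.
#'
#' @param seed base seed; every generator draws deterministically from it.
#' @param n_families_per_region,n_places_per_region study size.
#' @param settlement_mix multinomial mix over city/town/farm/unknown.
#' @param regions named list of `list(center = c(lat, lon), half = degrees)`
#'   box half-widths; regions must be disjoint.
#' @param median_birth_year,birth_year_sd proband birth-year distribution.
#' @param beta,gamma true hurdle coefficients, named by design column.
#' @param beta_settlement,gamma_settlement additional true settlement-size
#'   effects (town/farm/unknown vs. city), used by [simulate_dyads()].
#' @param sigma_S,sigma_T,sigma_U,sigma_V,sigma_E true scales.
#' @param delta true residence coefficients: matrix with design-column rows
#'   and neolocal/matrilocal/patrilocal columns.
#' @param sigma_W,rho_W scales and exchangeable correlation of the family
#'   residence intercept triples.
#' @param censor_rate fraction of grandparent birthplaces degraded to
#'   region-only knowledge.
#' @param missing_rate fraction of non-proband birthplaces deleted.
#' @param missing_dependence_or odds multiplier on grandparent missingness
#'   when the connecting parent migrated (1 = independent).
#' @param ancestry_alpha per-region Dirichlet parameters of the
#'   (Khoe-San, West/Central African, Eurasian) ancestry simplex.
#' @return list of class `kinloc_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_families_per_region = 150L,
                       n_places_per_region = 30L,
                       settlement_mix = c(city = 0.07, town = 0.38,
                                          farm = 0.40, unknown = 0.15),
                       regions = list(
                         Cederberg = list(center = c(-32.35, 19.00), half = 0.55),
                         Richtersveld = list(center = c(-28.80, 17.10), half = 0.55)),
                       median_birth_year = 1957, birth_year_sd = 15,
                       beta = NULL, gamma = NULL,
                       beta_settlement = c(town = 0, farm = 0, unknown = 0),
                       gamma_settlement = c(town = 0, farm = 0, unknown = 0),
                       sigma_S = 0.5, sigma_T = 1.0, sigma_U = 0.3,
                       sigma_V = 0.5, sigma_E = 0.9,
                       delta = NULL, sigma_W = c(0.3, 0.3, 0.3), rho_W = 0,
                       censor_rate = 0.2, missing_rate = 0.15,
                       missing_dependence_or = 1,
                       ancestry_alpha = list(
                         Cederberg = c(5.5, 1.5, 3.0),
                         Richtersveld = c(7.5, 0.5, 2.0))) {
  mig_cols <- c("intercept", "birth_year", "sex_male", "generation_parent",
                "region_Richtersveld", "sex_male:generation_parent",
                "sex_male:region_Richtersveld",
                "generation_parent:region_Richtersveld",
                "sex_male:generation_parent:region_Richtersveld")
  if (is.null(beta)) {
    beta <- stats::setNames(rep(0, 9), mig_cols)
    beta[c("intercept", "birth_year", "sex_male", "generation_parent",
           "region_Richtersveld")] <- c(-0.6, 0.15, 0.3, 0.5, 0.4)
  }
  if (is.null(gamma)) {
    gamma <- stats::setNames(rep(0, 9), mig_cols)
    gamma[c("intercept", "birth_year", "sex_male", "generation_parent",
            "region_Richtersveld")] <- c(log(60), 0.1, 0.25, -0.2, 0.35)
  }
  if (is.null(delta)) {
    res_cols <- c("intercept", "birth_year", "generation_parent",
                  "region_Richtersveld",
                  "generation_parent:region_Richtersveld")
    delta <- matrix(0, 5, 3,
                    dimnames = list(res_cols,
                                    c("neolocal", "matrilocal", "patrilocal")))
    delta["intercept", ] <- c(0.3, -0.5, -0.9)
    delta["birth_year", "neolocal"] <- 0.15
    delta["generation_parent", ] <- c(-0.6, -0.2, 0)
    delta["region_Richtersveld", "matrilocal"] <- 0.3
  }
  structure(list(
    seed = seed, n_families_per_region = n_families_per_region,
    n_places_per_region = n_places_per_region,
    settlement_mix = settlement_mix, regions = regions,
    median_birth_year = median_birth_year, birth_year_sd = birth_year_sd,
    beta = beta, gamma = gamma,
    beta_settlement = beta_settlement, gamma_settlement = gamma_settlement,
    sigma_S = sigma_S, sigma_T = sigma_T, sigma_U = sigma_U,
    sigma_V = sigma_V, sigma_E = sigma_E,
    delta = delta, sigma_W = sigma_W, rho_W = rho_W,
    censor_rate = censor_rate, missing_rate = missing_rate,
    missing_dependence_or = missing_dependence_or,
    ancestry_alpha = ancestry_alpha), class = "kinloc_sim_config")
}

.box_ring <- function(center, half) {
  data.frame(lat = center[1] + half * c(-1, -1, 1, 1),
             lon = center[2] + half * c(-1, 1, 1, -1))
}

#' Simulate a gazetteer and its region polygons
#'
#' @param config a [sim_config()].
#' @param seed seed override (default `config$seed`).
#' @return list with `gazetteer` and `polygons`; every birthplace lies
#'   strictly inside its region's polygon.
#' @export
simulate_gazetteer <- function(config, seed = config$seed) {
  set.seed(seed)
  polys <- lapply(config$regions, function(r) .box_ring(r$center, r$half))
  rn <- names(polys)
  for (i in seq_along(polys)) for (j in seq_len(i - 1L)) {
    a <- polys[[i]]; b <- polys[[j]]
    if (max(a$lat) > min(b$lat) && min(a$lat) < max(b$lat) &&
        max(a$lon) > min(b$lon) && min(a$lon) < max(b$lon)) {
      stop("region polygons overlap: ", rn[i], " and ", rn[j])
    }
  }
  margin <- 0.08
  rows <- lapply(rn, function(r) {
    ctr <- config$regions[[r]]$center; half <- config$regions[[r]]$half
    n <- config$n_places_per_region
    data.frame(
      place_id = sprintf("%s%02d", toupper(substr(r, 1, 3)), seq_len(n)),
      name = sprintf("%s settlement %d", r, seq_len(n)),
      lat = stats::runif(n, ctr[1] - half + margin, ctr[1] + half - margin),
      lon = stats::runif(n, ctr[2] - half + margin, ctr[2] + half - margin),
      region = r,
      settlement_size = sample(names(config$settlement_mix), n, replace = TRUE,
                               prob = config$settlement_mix),
      stringsAsFactors = FALSE)
  })
  list(gazetteer = do.call(rbind, rows), polygons = polys)
}

# true-covariate vector for a migration dyad, aligned with the baseline
# design columns (+ optional settlement dummies)
.mig_true_x <- function(byr_c, sex, generation, region) {
  sM <- as.numeric(sex == "male")
  gP <- as.numeric(generation == "parent")
  rR <- as.numeric(region == "Richtersveld")
  c(intercept = 1, birth_year = byr_c, sex_male = sM, generation_parent = gP,
    region_Richtersveld = rR, `sex_male:generation_parent` = sM * gP,
    `sex_male:region_Richtersveld` = sM * rR,
    `generation_parent:region_Richtersveld` = gP * rR,
    `sex_male:generation_parent:region_Richtersveld` = sM * gP * rR)
}

#' Simulate three-generation families through the hurdle model
#'
#' Places the proband at a random birthplace of the family's region, then
#' fills in the six migration dyads top-down (parents from the proband's
#' birthplace, each grandparent from the corresponding parent's): a
#' migration indicator is drawn from the logit sub-model, a distance from
#' the log-normal sub-model, and the mover is assigned the gazetteer place
#' whose great-circle distance from the anchor is nearest the drawn
#' distance.  Every dyad is therefore an exact draw from the model up to the
#' gazetteer's distance resolution.
#'
#' @param config a [sim_config()].
#' @param gazetteer,polygons from [simulate_gazetteer()].
#' @param seed seed override.
#' @return list with `persons` (fully exact birthplaces) and `truth`
#'   (drawn distances and indicators per dyad, varying intercepts, true
#'   parameters).
#' @export
simulate_families <- function(config, gazetteer, polygons,
                              seed = config$seed + 1L) {
  set.seed(seed)
  dm <- build_distance_matrix(gazetteer)
  rn <- names(config$regions)
  L <- config$n_families_per_region * length(rn)
  fam_ids <- sprintf("F%04d", seq_len(L))
  fam_region <- rep(rn, each = config$n_families_per_region)
  B <- nrow(gazetteer)
  S <- stats::setNames(stats::rnorm(L, 0, config$sigma_S), fam_ids)
  U <- stats::setNames(stats::rnorm(L, 0, config$sigma_U), fam_ids)
  TT <- stats::setNames(stats::rnorm(B, 0, config$sigma_T), gazetteer$place_id)
  V <- stats::setNames(stats::rnorm(B, 0, config$sigma_V), gazetteer$place_id)
  roles <- kinloc_roles()
  dy <- .dyads()
  mover_sex <- roles$sex[match(dy$mover, roles$role)]
  mover_gen <- roles$generation[match(dy$mover, roles$role)]
  reg_places_by <- lapply(rn, function(r) which(gazetteer$region == r))
  names(reg_places_by) <- rn
  # preallocated outputs
  p_place <- matrix(NA_integer_, 7, L, dimnames = list(roles$role, NULL))
  p_byr <- numeric(L); p_sex <- character(L)
  t_mig <- logical(L * 6); t_dstar <- numeric(L * 6); t_dtrue <- numeric(L * 6)
  t_anchor <- integer(L * 6)
  for (f in seq_len(L)) {
    fid <- fam_ids[f]
    byr <- round(stats::rnorm(1, config$median_birth_year, config$birth_year_sd))
    byr_c <- (byr - config$median_birth_year) / 10
    p_byr[f] <- byr
    p_place["proband", f] <- sample(reg_places_by[[fam_region[f]]], 1L)
    for (j in 1:6) {
      ai <- p_place[dy$anchor[j], f]
      x <- .mig_true_x(byr_c, mover_sex[j], mover_gen[j], gazetteer$region[ai])
      eta <- sum(x * config$beta) + S[fid] + TT[ai]
      migrated <- stats::runif(1) < stats::plogis(eta)
      k <- (f - 1L) * 6L + j
      t_anchor[k] <- ai; t_mig[k] <- migrated
      if (!migrated) {
        p_place[dy$mover[j], f] <- ai
      } else {
        mu <- sum(x * config$gamma) + U[fid] + V[ai]
        d_star <- exp(stats::rnorm(1, mu, config$sigma_E))
        cand <- abs(dm[ai, ] - d_star)
        cand[ai] <- Inf          # the mover left their child's birthplace
        mi <- which.min(cand)
        p_place[dy$mover[j], f] <- mi
        t_dstar[k] <- d_star; t_dtrue[k] <- dm[ai, mi]
      }
    }
    p_sex[f] <- sample(c("female", "male"), 1L)
  }
  role_rep <- rep(roles$role, L)
  fam_rep <- rep(fam_ids, each = 7)
  place_vec <- as.integer(p_place)
  persons <- data.frame(
    person_id = ifelse(role_rep == "proband", paste0("P", fam_rep),
                       paste(fam_rep, role_rep, sep = ":")),
    family_id = fam_rep, role = role_rep,
    sex = ifelse(role_rep == "proband", rep(p_sex, each = 7),
                 rep(roles$sex, L)),
    generation = rep(roles$generation, L), bk = "exact",
    place_id = gazetteer$place_id[place_vec],
    region_id = gazetteer$region[place_vec],
    birth_year = ifelse(role_rep == "proband", rep(p_byr, each = 7), NA_real_),
    sibling_group = NA_character_, stringsAsFactors = FALSE)
  truth_dyads <- data.frame(
    family_id = rep(fam_ids, each = 6),
    dyad = rep(paste(dy$anchor, dy$mover, sep = "-"), L),
    mover_role = rep(dy$mover, L),
    anchor_place = gazetteer$place_id[t_anchor],
    migrated = t_mig, d_star = t_dstar, d_true = t_dtrue,
    stringsAsFactors = FALSE)
  list(persons = persons,
       truth = list(dyads = truth_dyads,
                    S = S, T = TT, U = U, V = V,
                    params = config[c("beta", "gamma", "sigma_S", "sigma_T",
                                      "sigma_U", "sigma_V", "sigma_E")],
                    byr_center = config$median_birth_year))
}

#' Degrade simulated families into an observed dataset
#'
#' Applies the observation process: a fraction of grandparent birthplaces is
#' coarsened to region-only knowledge (producing censored dyads), and a
#' fraction of non-proband birthplaces is deleted outright, optionally with
#' higher odds of grandparent deletion when the connecting parent migrated
#' (informant knowledge of a grandparent's birthplace decays when the
#' family moved).  The truth record is never altered.
#'
#' @param sim output of [simulate_families()].
#' @param config a [sim_config()].
#' @param seed seed override.
#' @return list with degraded `persons` and the untouched `truth`.
#' @export
degrade <- function(sim, config, seed = config$seed + 2L) {
  set.seed(seed)
  p <- sim$persons
  gp <- grepl("grand", p$role)
  cens <- gp & stats::runif(nrow(p)) < config$censor_rate
  p$bk[cens] <- "region_only"
  p$place_id[cens] <- NA_character_
  # missingness, with optional dependence on the connecting parent's migration
  pr_miss <- ifelse(p$role == "proband", 0, config$missing_rate)
  if (config$missing_dependence_or != 1) {
    parent_of <- c(maternal_grandmother = "mother", maternal_grandfather = "mother",
                   paternal_grandmother = "father", paternal_grandfather = "father")
    key <- function(fid, role) paste(fid, role)
    moved <- new.env(parent = emptyenv())
    pro <- sim$persons[sim$persons$role == "proband", ]
    for (side in c("mother", "father")) {
      par <- sim$persons[sim$persons$role == side, ]
      mig <- par$place_id[match(pro$family_id, par$family_id)] != pro$place_id
      for (i in seq_len(nrow(pro))) {
        assign(key(pro$family_id[i], side), isTRUE(mig[i]), envir = moved)
      }
    }
    for (i in which(gp)) {
      side <- parent_of[[p$role[i]]]
      if (isTRUE(get0(key(p$family_id[i], side), envir = moved))) {
        o <- pr_miss[i] / (1 - pr_miss[i]) * config$missing_dependence_or
        pr_miss[i] <- o / (1 + o)
      }
    }
  }
  miss <- stats::runif(nrow(p)) < pr_miss
  p$bk[miss] <- "unknown"
  p$place_id[miss] <- NA_character_
  p$region_id[miss] <- NA_character_
  list(persons = p, truth = sim$truth)
}

#' Simulate residence outcomes from the multi-logit model
#'
#' Type-first generation: for every couple the residence type is drawn from
#' the multi-logit probabilities at the true coefficients and family
#' intercepts, and the couple's three birthplaces are then assigned within
#' the family's region consistently with the drawn type (so the residence
#' classifier reproduces it exactly; this is asserted and any mismatch is a
#' hard failure).  Birthplace intercepts are null in this generator because
#' birthplaces are assigned after the type.
#'
#' @param sim output of [simulate_families()] (supplies the family
#'   skeleton: ids, regions, proband birth years).
#' @param config a [sim_config()].
#' @param gazetteer gazetteer data frame.
#' @param seed seed override.
#' @return list with residence `outcomes` (schema of
#'   [build_residence_outcomes()]) and `truth` (`delta`, `W`, drawn types).
#' @export
simulate_residence_outcomes <- function(sim, config, gazetteer,
                                        seed = config$seed + 3L) {
  set.seed(seed)
  pro <- sim$persons[sim$persons$role == "proband", ]
  L <- nrow(pro)
  # family intercept triples with exchangeable correlation rho_W
  R <- matrix(config$rho_W, 3, 3); diag(R) <- 1
  A <- diag(config$sigma_W) %*% chol(R)
  W <- matrix(stats::rnorm(3 * L), L, 3) %*% A
  rownames(W) <- pro$family_id
  colnames(W) <- colnames(config$delta)
  couples <- data.frame(label = c("parents", "maternal_grandparents",
                                  "paternal_grandparents"),
                        generation = c("parent", "grandparent", "grandparent"),
                        stringsAsFactors = FALSE)
  lv <- c("equilocal", colnames(config$delta))
  rows <- vector("list", L * 3L)
  k <- 0L
  for (f in seq_len(L)) {
    fid <- pro$family_id[f]
    reg <- pro$region_id[f]
    byr <- pro$birth_year[f]
    byr_c <- (byr - config$median_birth_year) / 10
    reg_places <- gazetteer$place_id[gazetteer$region == reg]
    for (j in 1:3) {
      gP <- as.numeric(couples$generation[j] == "parent")
      rR <- as.numeric(reg == "Richtersveld")
      x <- c(intercept = 1, birth_year = byr_c, generation_parent = gP,
             region_Richtersveld = rR,
             `generation_parent:region_Richtersveld` = gP * rR)
      eta <- drop(x %*% config$delta[names(x), ]) + W[fid, ]
      pr <- residence_probs(eta)
      type <- sample(lv, 1L, prob = pr)
      p0 <- sample(reg_places, 1L)
      p1 <- sample(setdiff(reg_places, p0), 1L)
      if (type == "equilocal") {
        fe <- p0; ma <- p0; ch <- p0
      } else if (type == "matrilocal") {
        fe <- p0; ma <- p1; ch <- p0
      } else if (type == "patrilocal") {
        ma <- p0; fe <- p1; ch <- p0
      } else {
        fe <- p0; ma <- p1
        ch <- sample(setdiff(reg_places, c(p0, p1)), 1L)
      }
      got <- classify_residence(ch, fe, ma)
      if (!identical(got, type)) {
        stop("internal inconsistency: generated ", type, ", classified ", got)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        couple_id = paste(fid, couples$label[j], sep = ":"), family_id = fid,
        generation = couples$generation[j],
        child_place = ch, female_place = fe, male_place = ma,
        region = reg,
        child_settlement = gazetteer$settlement_size[
          match(ch, gazetteer$place_id)],
        type = type, proband_birth_year = byr, stringsAsFactors = FALSE)
    }
  }
  list(outcomes = do.call(rbind, rows[seq_len(k)]),
       truth = list(delta = config$delta, W = W, sigma_W = config$sigma_W,
                    rho_W = config$rho_W))
}

#' Simulate dyad-level migration outcomes with settlement-size effects
#'
#' Design-level generator used for covariate experiments: every dyad's
#' anchor and mover natal birthplaces are drawn up front within the family's
#' region (so the mover's settlement size is a true covariate), then the
#' migration indicator and distance are drawn from the hurdle model with the
#' configured settlement effects added.  Distances are model draws, not
#' map-consistent positions; the output feeds the design builders directly.
#'
#' @param config a [sim_config()] (set `beta_settlement`/`gamma_settlement`
#'   for non-null settlement effects).
#' @param gazetteer gazetteer data frame.
#' @param seed seed override.
#' @return list with migration `outcomes` and `truth`.
#' @export
simulate_dyads <- function(config, gazetteer, seed = config$seed + 4L) {
  set.seed(seed)
  rn <- names(config$regions)
  L <- config$n_families_per_region * length(rn)
  fam_ids <- sprintf("F%04d", seq_len(L))
  fam_region <- rep(rn, each = config$n_families_per_region)
  B <- nrow(gazetteer)
  S <- stats::rnorm(L, 0, config$sigma_S); U <- stats::rnorm(L, 0, config$sigma_U)
  TT <- stats::rnorm(B, 0, config$sigma_T); V <- stats::rnorm(B, 0, config$sigma_V)
  roles <- kinloc_roles(); dy <- .dyads()
  sett_eff <- function(tab, s) if (s %in% names(tab)) tab[[s]] else 0
  rows <- vector("list", L * 6L)
  k <- 0L
  for (f in seq_len(L)) {
    reg <- fam_region[f]
    byr <- round(stats::rnorm(1, config$median_birth_year, config$birth_year_sd))
    byr_c <- (byr - config$median_birth_year) / 10
    reg_places <- which(gazetteer$region == reg)
    for (j in seq_len(nrow(dy))) {
      ai <- sample(reg_places, 1L)
      mi <- sample(reg_places, 1L)
      mrole <- dy$mover[j]
      msex <- roles$sex[roles$role == mrole]
      mgen <- roles$generation[roles$role == mrole]
      sett <- gazetteer$settlement_size[mi]
      x <- .mig_true_x(byr_c, msex, mgen, reg)
      eta <- sum(x * config$beta) + sett_eff(config$beta_settlement, sett) +
        S[f] + TT[ai]
      mig <- stats::runif(1) < stats::plogis(eta)
      d <- 0
      if (mig) {
        mu <- sum(x * config$gamma) + sett_eff(config$gamma_settlement, sett) +
          U[f] + V[ai]
        d <- exp(stats::rnorm(1, mu, config$sigma_E))
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        person_id = paste(fam_ids[f], mrole, sep = ":"), family_id = fam_ids[f],
        dyad = paste(dy$anchor[j], mrole, sep = "-"),
        mover_sex = msex, mover_generation = mgen,
        anchor_place = gazetteer$place_id[ai], region = reg,
        mover_place = gazetteer$place_id[mi], mover_settlement = sett,
        status = "observed", d = d, d_min = NA_real_, d_max = NA_real_,
        migrated = ifelse(mig, "yes", "no"), proband_birth_year = byr,
        stringsAsFactors = FALSE)
    }
  }
  list(outcomes = do.call(rbind, rows[seq_len(k)]),
       truth = list(S = S, T = TT, U = U, V = V,
                    params = config[c("beta", "gamma", "beta_settlement",
                                      "gamma_settlement", "sigma_S", "sigma_T",
                                      "sigma_U", "sigma_V", "sigma_E")]))
}

#' Simulate per-proband ancestry proportions
#'
#' @param sim output of [simulate_families()].
#' @param config a [sim_config()] (per-region Dirichlet parameters).
#' @param seed seed override.
#' @return data frame `family_id, khoesan, westafrican, eurasian, ks_eu,
#'   wa_eu` with the log-ratio covariates attached.
#' @export
simulate_ancestry <- function(sim, config, seed = config$seed + 5L) {
  set.seed(seed)
  pro <- sim$persons[sim$persons$role == "proband", ]
  alpha <- t(vapply(pro$region_id, function(r) config$ancestry_alpha[[r]],
                    numeric(3)))
  g <- matrix(stats::rgamma(length(alpha), shape = alpha), ncol = 3)
  p <- g / rowSums(g)
  cv <- ancestry_covariates(p)
  data.frame(family_id = pro$family_id,
             khoesan = p[, 1], westafrican = p[, 2], eurasian = p[, 3],
             ks_eu = cv[, 1], wa_eu = cv[, 2], stringsAsFactors = FALSE)
}

#' Write simulated persons back to the genealogy-table schema
#' @param persons person records.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_genealogy <- function(persons, path) {
  roles <- kinloc_roles()
  cell <- function(p) {
    if (is.na(p$bk[1])) return("")
    switch(p$bk[1], exact = p$place_id[1], region_only = p$region_id[1],
           unknown = "", "")
  }
  fams <- unique(persons$family_id)
  rows <- lapply(fams, function(f) {
    fam <- persons[persons$family_id == f, ]
    pro <- fam[fam$role == "proband", ][1, ]
    vals <- lapply(seq_len(nrow(roles)), function(j) {
      m <- fam[fam$role == roles$role[j], ]
      if (nrow(m)) cell(m[1, ]) else ""
    })
    names(vals) <- roles$column
    c(list(family_id = f, proband_id = pro$person_id,
           sibling_group = ifelse(is.na(pro$sibling_group), "",
                                  pro$sibling_group),
           sex = pro$sex, birth_year = pro$birth_year), vals)
  })
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Simulate and write a complete study dataset
#'
#' Emits exactly the file schemas consumed by [read_genealogy()]:
#' `genealogy.csv`, `gazetteer.csv`, `regions.geojson`, `ancestry.csv`, plus
#' `truth.json` holding the generating parameters.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisible list of the in-memory objects.
#' @export
simulate_dataset <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gz <- simulate_gazetteer(config)
  sim <- simulate_families(config, gz$gazetteer, gz$polygons)
  obs <- degrade(sim, config)
  anc <- simulate_ancestry(sim, config)
  utils::write.csv(gz$gazetteer, file.path(dir, "gazetteer.csv"),
                   row.names = FALSE)
  write_region_polygons(gz$polygons, file.path(dir, "regions.geojson"))
  write_genealogy(obs$persons, file.path(dir, "genealogy.csv"))
  utils::write.csv(anc, file.path(dir, "ancestry.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed,
         params = sim$truth$params,
         delta = as.data.frame(config$delta)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(gazetteer = gz$gazetteer, polygons = gz$polygons,
                 persons = obs$persons, truth = sim$truth, ancestry = anc))
}
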