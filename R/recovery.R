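#' Parameter-recovery experiment
#'
#' Repeatedly simulates a study from known parameters, fits the requested
#' model(s) with shortened chains, and tabulates the bias of posterior
#' means, posterior SDs and 90% central-interval coverage for every true
#' fixed effect, plus the recovery of the variance components.  Replicates
#' whose sampler fails are recorded and excluded.
#'
#' @param config a [sim_config()] holding the truth.
#' @param n_replicates number of simulated studies.
#' @param models subset of `c("migration", "residence")`.
#' @param chains,warmup,iter chain configuration per fit (deliberately
#'   short; see the methods vignette for the rationale).
#' @param degrade_data apply the censoring/missingness layer before fitting
#'   the migration model.
#' @param quiet suppress per-replicate messages.
#' @return list with `fixed` (one row per replicate x fixed effect:
#'   truth, posterior mean/sd, 90% interval, coverage flag), `scales`
#'   (variance-component recovery) and `n_failed`.
#' @export
recovery_experiment <- function(config, n_replicates = 20L,
                                models = "migration",
                                chains = 2L, warmup = 300L, iter = 300L,
                                degrade_data = TRUE, quiet = TRUE) {
  fixed <- list(); scales <- list(); n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * r
    res <- tryCatch(
      .recovery_one(cfg, models, chains, warmup, iter, degrade_data),
      error = function(e) {
        if (!quiet) message("replicate ", r, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    res$fixed$replicate <- r
    res$scales$replicate <- r
    fixed[[length(fixed) + 1L]] <- res$fixed
    scales[[length(scales) + 1L]] <- res$scales
    if (!quiet) message("replicate ", r, " done")
  }
  list(fixed = do.call(rbind, fixed), scales = do.call(rbind, scales),
       n_failed = n_failed)
}

.recovery_one <- function(cfg, models, chains, warmup, iter, degrade_data) {
  gz <- simulate_gazetteer(cfg)
  sim <- simulate_families(cfg, gz$gazetteer, gz$polygons)
  fixed <- list(); scales <- list()
  fc <- fit_config(chains = chains, warmup = warmup, iter = iter,
                   seed = cfg$seed %% 100000L)
  if ("migration" %in% models) {
    obs <- if (degrade_data) degrade(sim, cfg) else sim
    dm <- build_distance_matrix(gz$gazetteer)
    out <- build_migration_outcomes(obs$persons, dm, gz$polygons, gz$gazetteer)
    des <- build_migration_design(out, byr_center = cfg$median_birth_year)
    ft <- suppressWarnings(fit(migration_model(des), fc))
    truth <- c(stats::setNames(cfg$beta, paste0("beta.", names(cfg$beta))),
               stats::setNames(cfg$gamma, paste0("gamma.", names(cfg$gamma))))
    sm <- summarize_draws(ft, pars = "^(beta|gamma)\\.")
    i <- match(sm$parameter, names(truth))
    fixed$migration <- data.frame(
      model = "migration", parameter = sm$parameter, truth = truth[i],
      mean = sm$mean, sd = sm$sd, q5 = sm$q5, q95 = sm$q95,
      bias = sm$mean - truth[i],
      cover90 = truth[i] >= sm$q5 & truth[i] <= sm$q95,
      stringsAsFactors = FALSE, row.names = NULL)
    ss <- summarize_draws(ft, pars = "^sigma_")
    struth <- c(sigma_S = cfg$sigma_S, sigma_T = cfg$sigma_T,
                sigma_U = cfg$sigma_U, sigma_V = cfg$sigma_V,
                sigma_E = cfg$sigma_E)
    scales$migration <- data.frame(
      model = "migration", parameter = ss$parameter,
      truth = struth[ss$parameter], mean = ss$mean,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if ("residence" %in% models) {
    ro <- simulate_residence_outcomes(sim, cfg, gz$gazetteer)
    des <- build_residence_design(ro$outcomes, byr_center = cfg$median_birth_year)
    ft <- suppressWarnings(fit(residence_model(des), fc))
    dt <- cfg$delta
    truth <- stats::setNames(
      as.numeric(dt),
      paste0("delta.", rep(colnames(dt), each = nrow(dt)), ".",
             rep(rownames(dt), ncol(dt))))
    sm <- summarize_draws(ft, pars = "^delta\\.")
    i <- match(sm$parameter, names(truth))
    fixed$residence <- data.frame(
      model = "residence", parameter = sm$parameter, truth = truth[i],
      mean = sm$mean, sd = sm$sd, q5 = sm$q5, q95 = sm$q95,
      bias = sm$mean - truth[i],
      cover90 = truth[i] >= sm$q5 & truth[i] <= sm$q95,
      stringsAsFactors = FALSE, row.names = NULL)
    ss <- summarize_draws(ft, pars = "^sigma_W")
    scales$residence <- data.frame(
      model = "residence", parameter = ss$parameter,
      truth = rep(cfg$sigma_W, length.out = nrow(ss)), mean = ss$mean,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  list(fixed = do.call(rbind, fixed), scales = do.call(rbind, scales))
}
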