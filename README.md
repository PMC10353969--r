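# kinloc

Hierarchical Bayesian models of intergenerational migration and
postmarital residence for proband-anchored, three-generation genealogies.

## The problem

In ethnographic interview studies of kin migration, each interviewed
participant (the *proband*) reports birthplaces for themselves, their
parents and their four grandparents.  From these, two outcome layers can be
built:

* **migration**: up to six parent–child dyads per family, where the elder
  member's migration distance is the great-circle distance between the two
  birthplaces.  Informants often know a forebear's birthplace only at the
  regional level, so distances may be known only to lie in an interval
  derived from the region polygon — and when the two regions coincide, even
  whether migration happened at all is latent;
* **postmarital residence**: up to three couples per family, typed from
  shared birthplaces as *equilocal* (child born where both parents were),
  *matrilocal* (mother only), *patrilocal* (father only) or *neolocal*
  (neither).

kinloc builds both outcome layers from genealogy/gazetteer/polygon files,
fits the two models below with its own gradient-based no-U-turn sampler,
and compares covariate variants by PSIS-LOO.  Because such field data are
rarely deposited, a first-class synthetic-data module generates complete
studies (including the censoring and missingness process) from known
parameters, so every stage is testable end to end.

## The models

Migration is a two-part (hurdle) outcome.  For dyad *i* in family *l(i)*
with anchor birthplace *b(i)*:

    logit(pi_i) = x_i' beta + S_l(i) + T_b(i)
    log d_i | migrated = x_i' gamma + U_l(i) + V_b(i) + E_i,  E_i ~ N(0, sigma_E)

with density `1 - pi` at `d = 0` and `pi * LogNormal(d)` for `d > 0`;
censored dyads contribute the integral over their interval, and
latent-status dyads contribute `(1 - pi) + pi * P(d <= d_max)`.
Covariates: proband birth year (centred), full factorial of mover sex ×
generation × region; variants add settlement-size dummies of the mover's
birthplace or the proband's ancestry log-ratios.

Residence is a multinomial logit against the equilocal reference, for
couple *c* with male/female birthplaces `b_m(c)`, `b_f(c)`:

    log(pi_rc / pi_ec) = x_c' delta_r + W_r,l(c) + Y_r,bm(c) + Z_r,bf(c)

Priors: multivariate Gaussians on the coefficient blocks with
half-Cauchy(0,1) scale and LKJ(2) correlation decompositions (the gamma
prior mean starts at log 100 km); zero-mean Gaussians with half-Cauchy
scales on all varying intercepts; the residence coefficient vector and
each intercept triple are correlated across the three non-reference types.
See `vignettes/kinloc-methods.Rmd` for the full account.

## Worked example

```r
library(kinloc)

cfg <- sim_config(seed = 2024, n_families_per_region = 60, n_places_per_region = 20)
gz  <- simulate_gazetteer(cfg)
sim <- simulate_families(cfg, gz$gazetteer, gz$polygons)
obs <- degrade(sim, cfg)                       # censoring + missingness
dm  <- build_distance_matrix(gz$gazetteer)
mig <- build_migration_outcomes(obs$persons, dm, gz$polygons, gz$gazetteer)
res <- build_residence_outcomes(obs$persons, gz$gazetteer)
summarize_outcomes(mig, res)$overall
#> $n_complete      [1] 488
#> $prop_migrated   [1] 0.508
#> $median_km       [1] 73.2
#> $iqr_km          [1] 61.4
#> $n_typed_couples [1] 188
#> $nonequilocal_shares
#>   neolocal matrilocal patrilocal
#>      0.441      0.265      0.294

des <- build_migration_design(mig)
ft  <- fit(migration_model(des),
           fit_config(chains = 2, warmup = 300, iter = 300, seed = 1))
summarize_draws(ft, pars = "^beta[.](intercept|birth_year|region)|^sigma_[TE]")
#>                  parameter   mean    sd     q5  q95 rhat well_supported
#> 1           beta.intercept -0.071 0.218 -0.480 0.27    1          FALSE
#> 2          beta.birth_year  0.046 0.072 -0.066 0.18    1          FALSE
#> 3 beta.region_Richtersveld -0.034 0.290 -0.533 0.42    1          FALSE
#> 4                  sigma_T  1.205 0.206  0.905 1.57    1           TRUE
#> 5                  sigma_E  0.891 0.058  0.796 0.99    1           TRUE
```

Half the complete-case movers migrated, with a median distance of 73 km
(the generating truth puts the reference-cell median at 60 km with strong
birthplace heterogeneity, `sigma_T = 1`).  The fitted residual scale of the
log-distance (`sigma_E` 0.89, truth 0.9) and the birthplace log-odds scale
(`sigma_T` 1.21, truth 1.0) bracket their generating values at this small
study size; `well_supported` flags parameters whose central 90% interval
excludes zero.  Chains this short are for illustration — `fit_config()`
defaults to 4 chains with 6,500 warmup and 1,500 kept draws.

`marginalize_birthplace_effects(ft)` returns posterior draws of the odds
of migration and the median distance per region × generation × sex,
marginalized over birthplace intercepts with the cells' empirical
birthplace frequencies as weights — the quantity usually displayed as
posterior density strips.

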