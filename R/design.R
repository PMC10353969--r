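#' Ancestry log-ratio covariates
#'
#' Converts per-proband ancestry proportions (Khoe-San, West/Central African,
#' Eurasian; a 3-simplex) into the two ratio covariates used by the ancestry
#' model variants: Khoe-San relative to Eurasian and West/Central African
#' relative to Eurasian.  Components are floored at `eps` and renormalized so
#' degenerate simplices stay finite.  The default transform is the additive
#' log-ratio; `log = FALSE` gives raw ratios.
#'
#' @param proportions matrix/data frame with three columns in the order
#'   Khoe-San, West/Central African, Eurasian; rows sum to 1 (tolerance 1e-6).
#' @param eps flooring constant.
#' @param log use log ratios (default) or raw ratios.
#' @return two-column matrix `(ks_eu, wa_eu)`.
#' @export
ancestry_covariates <- function(proportions, eps = 0.001, log = TRUE) {
  p <- as.matrix(proportions)
  if (ncol(p) != 3) stop("ancestry proportions must have 3 components")
  if (any(p < 0)) stop("ancestry proportions must be nonnegative")
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("ancestry proportions must sum to 1 (tolerance 1e-6)")
  }
  p <- pmax(p, eps)
  p <- p / rowSums(p)
  r <- cbind(ks_eu = p[, 1] / p[, 3], wa_eu = p[, 2] / p[, 3])
  if (log) base::log(r) else r
}

.dummy <- function(x, ref, prefix) {
  lev <- setdiff(sort(unique(x)), ref)
  m <- vapply(lev, function(l) as.numeric(x == l), numeric(length(x)))
  m <- matrix(m, nrow = length(x))
  colnames(m) <- paste0(prefix, lev)
  m
}

.settlement_dummies <- function(x) {
  lev <- c("town", "farm", "unknown")   # reference: city
  m <- vapply(lev, function(l) as.numeric(x == l), numeric(length(x)))
  m <- matrix(m, nrow = length(x))
  colnames(m) <- paste0("settlement_", lev)
  m
}

.join_ancestry <- function(family_id, ancestry) {
  if (is.null(ancestry)) {
    stop("variant 'ancestry' requires an ancestry covariate table")
  }
  i <- match(family_id, ancestry$family_id)
  if (anyNA(i)) stop("ancestry table lacks families: ",
                     paste(unique(family_id[is.na(i)]), collapse = ", "))
  cbind(ancestry_ks_eu = ancestry$ks_eu[i], ancestry_wa_eu = ancestry$wa_eu[i])
}

#' Covariate design for the migration hurdle model
#'
#' Builds the shared covariate matrix of both hurdle sub-models: intercept,
#' the proband's birth year (centred at the sample median, per decade), and
#' the full factorial of the mover's sex and generation with region (dummies,
#' all pairwise interactions and the three-way interaction).  Reference cell:
#' female grandparents in the reference region.  Outcomes with `status ==
#' "missing"` are dropped; family and anchor-birthplace indices are made
#' contiguous.
#'
#' @param outcomes migration outcomes from [build_migration_outcomes()].
#' @param variant `"baseline"`, `"settlement_size"` (adds dummies for the
#'   mover's birthplace size, reference city) or `"ancestry"` (adds the two
#'   ancestry ratio covariates).
#' @param ancestry data frame `family_id, ks_eu, wa_eu` (see
#'   [ancestry_covariates()]); required for the ancestry variant.
#' @param ref_region reference region level.
#' @param byr_center centre for the birth-year covariate; defaults to the
#'   median proband birth year of the retained outcomes.
#' @return object of class `kinloc_design` with the design matrix `X`,
#'   filtered `outcomes`, and contiguous `family` / `place` indices.
#' @export
build_migration_design <- function(outcomes,
                                   variant = c("baseline", "settlement_size",
                                               "ancestry"),
                                   ancestry = NULL,
                                   ref_region = "Cederberg",
                                   byr_center = NULL) {
  variant <- match.arg(variant)
  o <- outcomes[outcomes$status != "missing" & !is.na(outcomes$anchor_place), ,
                drop = FALSE]
  if (!nrow(o)) stop("no non-missing migration outcomes")
  if (!ref_region %in% o$region) ref_region <- sort(unique(o$region))[1]
  if (is.null(byr_center)) {
    byr_center <- stats::median(o$proband_birth_year, na.rm = TRUE)
  }
  byr <- (o$proband_birth_year - byr_center) / 10
  byr[is.na(byr)] <- 0
  sexM <- as.numeric(o$mover_sex == "male")
  genP <- as.numeric(o$mover_generation == "parent")
  reg <- .dummy(o$region, ref_region, "region_")
  X <- cbind(intercept = 1, birth_year = byr, sex_male = sexM,
             generation_parent = genP, reg,
             `sex_male:generation_parent` = sexM * genP)
  if (ncol(reg)) {
    for (r in colnames(reg)) {
      extra <- cbind(sexM * reg[, r], genP * reg[, r], sexM * genP * reg[, r])
      colnames(extra) <- paste0(c("sex_male:", "generation_parent:",
                                  "sex_male:generation_parent:"), r)
      X <- cbind(X, extra)
    }
  }
  if (variant == "settlement_size") {
    X <- cbind(X, .settlement_dummies(o$mover_settlement))
  } else if (variant == "ancestry") {
    X <- cbind(X, .join_ancestry(o$family_id, ancestry))
  }
  fam_lev <- sort(unique(o$family_id))
  plc_lev <- sort(unique(o$anchor_place))
  structure(list(
    X = X, outcomes = o,
    family = match(o$family_id, fam_lev),
    place = match(o$anchor_place, plc_lev),
    family_levels = fam_lev, place_levels = plc_lev,
    variant = variant, byr_center = byr_center,
    ref = list(region = ref_region, sex = "female", generation = "grandparent")
  ), class = "kinloc_design")
}

#' Covariate design for the postmarital residence model
#'
#' Intercept, centred proband birth year, and the full factorial of
#' generation (parental vs. grandparental couples) with region.  The couple's
#' place of postmarital residence is operationalized as the child's
#' birthplace, whose settlement size feeds the settlement variant.  Couples
#' with `type == "missing"` are excluded.
#'
#' @inheritParams build_migration_design
#' @param outcomes residence outcomes from [build_residence_outcomes()].
#' @param ref_type reference residence category for the multi-logit.
#' @return object of class `kinloc_res_design`, with male and female
#'   birthplace indices (`male_place`, `female_place`) and the observed type
#'   coded against `type_levels` (`ref_type` first).
#' @export
build_residence_design <- function(outcomes,
                                   variant = c("baseline", "settlement_size",
                                               "ancestry"),
                                   ancestry = NULL,
                                   ref_region = "Cederberg",
                                   ref_type = "equilocal",
                                   byr_center = NULL) {
  variant <- match.arg(variant)
  o <- outcomes[outcomes$type != "missing", , drop = FALSE]
  if (!nrow(o)) stop("no typed residence outcomes")
  if (!ref_region %in% o$region) ref_region <- sort(unique(o$region))[1]
  if (is.null(byr_center)) {
    byr_center <- stats::median(o$proband_birth_year, na.rm = TRUE)
  }
  byr <- (o$proband_birth_year - byr_center) / 10
  byr[is.na(byr)] <- 0
  genP <- as.numeric(o$generation == "parent")
  reg <- .dummy(o$region, ref_region, "region_")
  X <- cbind(intercept = 1, birth_year = byr, generation_parent = genP, reg)
  if (ncol(reg)) {
    for (r in colnames(reg)) {
      X <- cbind(X, genP * reg[, r])
      colnames(X)[ncol(X)] <- paste0("generation_parent:", r)
    }
  }
  if (variant == "settlement_size") {
    X <- cbind(X, .settlement_dummies(o$child_settlement))
  } else if (variant == "ancestry") {
    X <- cbind(X, .join_ancestry(o$family_id, ancestry))
  }
  lv <- c(ref_type, setdiff(kinloc_residence_levels(), ref_type))
  fam_lev <- sort(unique(o$family_id))
  male_lev <- sort(unique(o$male_place))
  female_lev <- sort(unique(o$female_place))
  structure(list(
    X = X, outcomes = o,
    y = match(o$type, lv),
    type_levels = lv,
    family = match(o$family_id, fam_lev),
    male_place = match(o$male_place, male_lev),
    female_place = match(o$female_place, female_lev),
    family_levels = fam_lev, male_levels = male_lev, female_levels = female_lev,
    variant = variant, byr_center = byr_center,
    ref = list(region = ref_region, generation = "grandparent",
               type = ref_type)
  ), class = "kinloc_res_design")
}
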