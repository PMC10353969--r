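# Posterior cell effects marginalized over birthplace varying intercepts.

# covariate vector for a region x generation x sex cell at the reference
# birth year; variant columns (settlement, ancestry) are held at their
# reference/centre values (zero)
.mig_cell_x <- function(design, region, generation, sex) {
  base <- c(intercept = 1, birth_year = 0,
            sex_male = as.numeric(sex == "male"),
            generation_parent = as.numeric(generation == "parent"))
  reg <- paste0("region_", region)
  vapply(colnames(design$X), function(cn) {
    parts <- strsplit(cn, ":", fixed = TRUE)[[1]]
    prod(vapply(parts, function(p) {
      if (p %in% names(base)) base[[p]]
      else if (startsWith(p, "region_")) as.numeric(p == reg)
      else 0
    }, numeric(1)))
  }, numeric(1))
}

#' Marginal posterior odds and distances per region x generation x sex cell
#'
#' For every posterior draw and cell, computes the predicted odds of
#' migration and the predicted median migration distance as a weighted
#' mixture over the cell's birthplace varying intercepts, with the relative
#' frequencies of birthplaces in the cell as weights, at the reference
#' (sample median) birth year and with family intercepts at zero.  This is
#' the quantity displayed as posterior density strips by cell.
#'
#' @param fit a `kinloc_fit` of a migration model.
#' @param weights optional named list `cell -> named numeric` of birthplace
#'   weights (summing to 1); by default the empirical birthplace frequencies
#'   of each cell in the fitted outcomes.
#' @return long data frame with `region`, `generation`, `sex`, `draw`,
#'   `odds` and `distance_km` columns.
#' @export
marginalize_birthplace_effects <- function(fit, weights = NULL) {
  design <- fit$model$design
  stopifnot(inherits(design, "kinloc_design"))
  o <- design$outcomes
  dr <- fit$draws
  S <- dim(dr)[1] * dim(dr)[2]
  flat <- function(cols) {
    m <- matrix(dr[, , cols], S, length(cols))
    colnames(m) <- cols
    m
  }
  pn <- dimnames(dr)[[3]]
  beta <- flat(grep("^beta\\.", pn, value = TRUE))
  gamma <- flat(grep("^gamma\\.", pn, value = TRUE))
  Tm <- flat(grep("^T\\.", pn, value = TRUE))
  Vm <- flat(grep("^V\\.", pn, value = TRUE))
  cells <- unique(o[, c("region", "mover_generation", "mover_sex")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    key <- paste(cl$region, cl$mover_generation, cl$mover_sex, sep = ".")
    sel <- o$region == cl$region & o$mover_generation == cl$mover_generation &
      o$mover_sex == cl$mover_sex
    if (!any(sel)) {
      warning("empty cell omitted: ", key)
      next
    }
    if (is.null(weights) || is.null(weights[[key]])) {
      tb <- table(o$anchor_place[sel])
      w <- as.numeric(tb) / sum(tb)
      names(w) <- names(tb)
    } else {
      w <- weights[[key]]
    }
    if (abs(sum(w) - 1) > 1e-8) stop("cell weights must sum to 1: ", key)
    x <- .mig_cell_x(design, cl$region, cl$mover_generation, cl$mover_sex)
    ti <- match(paste0("T.", names(w)), colnames(Tm))
    vi <- match(paste0("V.", names(w)), colnames(Vm))
    mixT <- drop(exp(Tm[, ti, drop = FALSE]) %*% w)
    mixV <- drop(exp(Vm[, vi, drop = FALSE]) %*% w)
    out[[key]] <- data.frame(
      region = cl$region, generation = cl$mover_generation, sex = cl$mover_sex,
      draw = seq_len(S),
      odds = exp(drop(beta %*% x)) * mixT,
      distance_km = exp(drop(gamma %*% x)) * mixV,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
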