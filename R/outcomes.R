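#' Classify postmarital residence from three birthplaces
#'
#' Residence type is defined from shared birthplaces: a child born in the
#' same place as both parents is *equilocal*; same place as the mother only,
#' *matrilocal*; same place as the father only, *patrilocal*; a different
#' place from both, *neolocal*.  Identity is judged at `place_id` resolution,
#' so a couple can only be typed when all three birthplaces are exactly
#' known; any unknown (or region-only) birthplace makes the comparison
#' undecidable and the outcome `missing`.
#'
#' @param child_place,mother_place,father_place character vectors of
#'   gazetteer place ids; `NA` or `"unknown"` marks an unknown birthplace.
#' @return character vector over
#'   `{equilocal, neolocal, matrilocal, patrilocal, missing}`.
#' @export
classify_residence <- function(child_place, mother_place, father_place) {
  n <- max(length(child_place), length(mother_place), length(father_place))
  ch <- rep_len(as.character(child_place), n)
  mo <- rep_len(as.character(mother_place), n)
  fa <- rep_len(as.character(father_place), n)
  unk <- function(x) is.na(x) | x == "unknown"
  out <- rep("missing", n)
  ok <- !(unk(ch) | unk(mo) | unk(fa))
  sm <- ch[ok] == mo[ok]
  sf <- ch[ok] == fa[ok]
  out[ok] <- ifelse(sm & sf, "equilocal",
             ifelse(sm & !sf, "matrilocal",
             ifelse(!sm & sf, "patrilocal", "neolocal")))
  out
}

kinloc_residence_levels <- function() {
  c("equilocal", "neolocal", "matrilocal", "patrilocal")
}

.dyads <- function() {
  data.frame(
    anchor = c("proband", "proband", "mother", "mother", "father", "father"),
    mover = c("mother", "father", "maternal_grandmother", "maternal_grandfather",
              "paternal_grandmother", "paternal_grandfather"),
    stringsAsFactors = FALSE
  )
}

#' Construct intergenerational migration outcomes
#'
#' Each family contributes up to six parent-child dyads (proband vs. each
#' parent; each parent vs. their own parents).  The modelled mover is the
#' elder member; the anchor birthplace is the younger member's, and the
#' migration distance is the great-circle distance between the two
#' birthplaces.  A mover whose birthplace is known only at regional level
#' yields an interval-censored outcome: when the regions agree the distance
#' is bounded by `(0, d_max)` and the migration indicator itself is latent
#' (`status_unknown_censored`); when they differ the distance lies in
#' `(d_min, d_max)` with both bounds from the region polygon and migration
#' certain.  Dyads with an unknown endpoint, or whose anchor birthplace is
#' not exactly known, are `missing`.
#'
#' @param persons person records (see [read_genealogy()]).
#' @param distmatrix distance matrix from [build_distance_matrix()].
#' @param polygons named list of region polygon rings.
#' @param gazetteer gazetteer data frame (anchor coordinates and mover
#'   settlement sizes are looked up here).
#' @return data frame of migration outcomes, one row per dyad.
#' @export
build_migration_outcomes <- function(persons, distmatrix, polygons, gazetteer) {
  dy <- .dyads()
  roles <- kinloc_roles()$role
  fams <- unique(persons$family_id)
  nf <- length(fams)
  key <- paste(persons$family_id, persons$role, sep = "\r")
  im <- matrix(match(paste(rep(fams, each = length(roles)),
                           rep(roles, nf), sep = "\r"), key),
               nrow = length(roles),
               dimnames = list(roles, NULL))
  byr <- persons$birth_year[im["proband", ]]
  boundaries <- lapply(polygons, densify_ring)
  # censoring bounds cached per (anchor place, mover region) pair
  bcache <- new.env(parent = emptyenv())
  get_bounds <- function(place, region) {
    ck <- paste(place, region)
    b <- get0(ck, envir = bcache)
    if (is.null(b)) {
      g <- gazetteer[match(place, gazetteer$place_id), ]
      b <- censoring_bounds(c(g$lat, g$lon), polygons[[region]],
                            boundary = boundaries[[region]])
      assign(ck, b, envir = bcache)
    }
    b
  }
  out <- vector("list", nrow(dy))
  for (j in seq_len(nrow(dy))) {
    a <- persons[im[dy$anchor[j], ], ]
    m <- persons[im[dy$mover[j], ], ]
    status <- rep("missing", nf)
    d <- dmin <- dmax <- rep(NA_real_, nf)
    migrated <- rep("unknown", nf)
    obs <- a$bk %in% "exact" & m$bk %in% "exact"
    if (any(obs)) {
      d[obs] <- distmatrix[cbind(match(a$place_id[obs], rownames(distmatrix)),
                                 match(m$place_id[obs], colnames(distmatrix)))]
      same <- obs & a$place_id == m$place_id
      d[same] <- 0
      status[obs] <- "observed"
      migrated[obs] <- ifelse(same[obs], "no", "yes")
    }
    cz <- which(a$bk %in% "exact" & m$bk %in% "region_only" &
                  m$region_id %in% names(polygons))
    for (i in cz) {
      b <- get_bounds(a$place_id[i], m$region_id[i])
      if (identical(a$region_id[i], m$region_id[i]) || b[["d_min"]] <= 0) {
        status[i] <- "status_unknown_censored"
        dmin[i] <- 0; dmax[i] <- b[["d_max"]]
      } else {
        status[i] <- "interval_censored"
        dmin[i] <- b[["d_min"]]; dmax[i] <- b[["d_max"]]
        migrated[i] <- "yes"
      }
    }
    sett <- rep("unknown", nf)
    mex <- m$bk %in% "exact"
    sett[mex] <- gazetteer$settlement_size[
      match(m$place_id[mex], gazetteer$place_id)]
    out[[j]] <- data.frame(
      person_id = m$person_id, family_id = fams,
      dyad = paste(dy$anchor[j], dy$mover[j], sep = "-"),
      mover_sex = m$sex, mover_generation = m$generation,
      anchor_place = ifelse(a$bk == "exact", a$place_id, NA_character_),
      region = a$region_id,
      mover_place = m$place_id, mover_settlement = sett,
      status = status, d = d, d_min = dmin, d_max = dmax,
      migrated = migrated, proband_birth_year = byr,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  # family-major ordering (the six dyads grouped within family)
  res <- res[order(match(res$family_id, fams),
                   match(res$dyad, paste(dy$anchor, dy$mover, sep = "-"))), ]
  rownames(res) <- NULL
  res
}

#' Construct postmarital residence outcomes
#'
#' Up to three couples per family: the proband's parents, the maternal
#' grandparents and the paternal grandparents, typed by comparing the
#' child's birthplace with both members of the couple.  Couples with any
#' inexact birthplace are `missing` and flagged for exclusion from fitting.
#'
#' @param persons person records.
#' @param gazetteer optional gazetteer; if supplied, the settlement size of
#'   the child's birthplace (the couple's postmarital settlement) is
#'   attached for the settlement-size model variant.
#' @return data frame of residence outcomes, one row per couple.
#' @export
build_residence_outcomes <- function(persons, gazetteer = NULL) {
  couples <- data.frame(
    label = c("parents", "maternal_grandparents", "paternal_grandparents"),
    child = c("proband", "mother", "father"),
    female = c("mother", "maternal_grandmother", "paternal_grandmother"),
    male = c("father", "maternal_grandfather", "paternal_grandfather"),
    generation = c("parent", "grandparent", "grandparent"),
    stringsAsFactors = FALSE
  )
  roles <- kinloc_roles()$role
  fams <- unique(persons$family_id)
  nf <- length(fams)
  key <- paste(persons$family_id, persons$role, sep = "\r")
  im <- matrix(match(paste(rep(fams, each = length(roles)),
                           rep(roles, nf), sep = "\r"), key),
               nrow = length(roles), dimnames = list(roles, NULL))
  byr <- persons$birth_year[im["proband", ]]
  out <- vector("list", 3L)
  for (j in 1:3) {
    ch <- persons[im[couples$child[j], ], ]
    fe <- persons[im[couples$female[j], ], ]
    ma <- persons[im[couples$male[j], ], ]
    pid <- function(p) ifelse(p$bk %in% "exact", p$place_id, NA_character_)
    cp <- pid(ch); fp <- pid(fe); mp <- pid(ma)
    sett <- rep("unknown", nf)
    if (!is.null(gazetteer)) {
      cex <- ch$bk %in% "exact"
      sett[cex] <- gazetteer$settlement_size[
        match(ch$place_id[cex], gazetteer$place_id)]
    }
    out[[j]] <- data.frame(
      couple_id = paste(fams, couples$label[j], sep = ":"), family_id = fams,
      generation = couples$generation[j],
      child_place = cp, female_place = fp, male_place = mp,
      region = ch$region_id, child_settlement = sett,
      type = classify_residence(cp, fp, mp), proband_birth_year = byr,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$family_id, fams),
                   match(res$generation, c("parent", "grandparent"))), ]
  rownames(res) <- NULL
  res
}

#' Descriptive summaries of migration and residence outcomes
#'
#' @param migration migration outcomes from [build_migration_outcomes()],
#'   or `NULL`.
#' @param residence residence outcomes from [build_residence_outcomes()],
#'   or `NULL`.
#' @return list with `migration` (per region x generation x sex: proportion
#'   migrated among complete cases; median and IQR of positive observed
#'   distances), `residence` (per region x generation: residence-type
#'   proportions among non-missing couples) and `overall` headline numbers.
#' @export
summarize_outcomes <- function(migration = NULL, residence = NULL) {
  out <- list()
  if (!is.null(migration)) {
    obs <- migration[migration$status == "observed", ]
    spl <- split(obs, list(obs$region, obs$mover_generation, obs$mover_sex),
                 drop = TRUE)
    out$migration <- do.call(rbind, lapply(names(spl), function(nm) {
      g <- spl[[nm]]
      mv <- g$d[g$d > 0]
      data.frame(cell = nm, n = nrow(g),
                 prop_migrated = mean(g$d > 0),
                 median_km = if (length(mv)) stats::median(mv) else NA_real_,
                 iqr_km = if (length(mv)) stats::IQR(mv) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    mv <- obs$d[obs$d > 0]
    out$overall <- list(
      n_complete = nrow(obs),
      prop_migrated = if (nrow(obs)) mean(obs$d > 0) else NA_real_,
      median_km = if (length(mv)) stats::median(mv) else NA_real_,
      iqr_km = if (length(mv)) stats::IQR(mv) else NA_real_
    )
  }
  if (!is.null(residence)) {
    typed <- residence[residence$type != "missing", ]
    spl <- split(typed, list(typed$region, typed$generation), drop = TRUE)
    lv <- kinloc_residence_levels()
    out$residence <- do.call(rbind, lapply(names(spl), function(nm) {
      g <- spl[[nm]]
      p <- as.list(prop.table(table(factor(g$type, levels = lv))))
      cbind(data.frame(cell = nm, n = nrow(g), stringsAsFactors = FALSE),
            as.data.frame(p))
    }))
    out$overall$n_typed_couples <- nrow(typed)
    if (nrow(typed)) {
      nonequi <- typed$type[typed$type != "equilocal"]
      out$overall$residence_shares <- prop.table(table(factor(typed$type, levels = lv)))
      out$overall$nonequilocal_shares <-
        prop.table(table(factor(nonequi, levels = lv[-1])))
    }
  }
  out
}
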