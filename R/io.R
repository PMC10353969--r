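#' @keywords internal
kinloc_roles <- function() {
  data.frame(
    role = c("proband", "mother", "father",
             "maternal_grandmother", "maternal_grandfather",
             "paternal_grandmother", "paternal_grandfather"),
    sex = c(NA, "female", "male", "female", "male", "female", "male"),
    generation = c("proband", "parent", "parent",
                   "grandparent", "grandparent", "grandparent", "grandparent"),
    column = c("birthplace", "mother_birthplace", "father_birthplace",
               "mgm_birthplace", "mgf_birthplace",
               "pgm_birthplace", "pgf_birthplace"),
    stringsAsFactors = FALSE
  )
}

kinloc_settlement_levels <- function() c("city", "town", "farm", "unknown")

#' Read and validate a birthplace gazetteer
#'
#' @param path CSV with columns `place_id, name, lat, lon, region,
#'   settlement_size`.
#' @return validated data frame.
#' @export
read_gazetteer <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("place_id", "name", "lat", "lon", "region", "settlement_size")
  miss <- setdiff(req, names(g))
  if (length(miss)) stop("gazetteer lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(g$place_id)) {
    stop("duplicate place_id in gazetteer: ",
         paste(unique(g$place_id[duplicated(g$place_id)]), collapse = ", "))
  }
  .check_coords(cbind(g$lat, g$lon))
  bad <- setdiff(unique(g$settlement_size), kinloc_settlement_levels())
  if (length(bad)) {
    stop("settlement_size must be one of city/town/farm/unknown; found: ",
         paste(bad, collapse = ", "))
  }
  g
}

#' Read region polygons from GeoJSON
#'
#' Expects a FeatureCollection with one Polygon feature per region carrying a
#' `region_id` property.  Only the outer ring is used.
#'
#' @param path GeoJSON file.
#' @return named list of data frames with columns `lat`, `lon`.
#' @export
read_region_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  out <- list()
  for (f in gj$features) {
    rid <- f$properties$region_id
    if (is.null(rid)) stop("feature lacks a region_id property")
    if (!identical(f$geometry$type, "Polygon")) {
      stop("region ", rid, ": geometry must be a Polygon")
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(xy) c(lat = xy[[2]], lon = xy[[1]])))
    df <- as.data.frame(m)
    if (nrow(df) >= 2 && all(df[1, ] == df[nrow(df), ])) df <- df[-nrow(df), ]
    if (nrow(df) < 3) stop("region ", rid, ": ring needs at least 3 vertices")
    out[[as.character(rid)]] <- df
  }
  out
}

#' Write region polygons as GeoJSON
#' @param polygons named list of data frames with `lat`, `lon`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_polygons <- function(polygons, path) {
  feats <- lapply(names(polygons), function(rid) {
    df <- polygons[[rid]]
    ring <- lapply(seq_len(nrow(df)), function(i) c(df$lon[i], df$lat[i]))
    ring <- c(ring, ring[1])
    list(type = "Feature",
         properties = list(region_id = rid),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.norm_place <- function(x) tolower(trimws(x))

# classify one birthplace cell against gazetteer + polygons:
# returns list(bk, place_id, region_id)
.resolve_place <- function(cell, gazetteer, polygons) {
  if (is.na(cell) || !nzchar(trimws(cell))) {
    return(list(bk = "unknown", place_id = NA_character_, region_id = NA_character_))
  }
  hit <- match(trimws(cell), trimws(gazetteer$place_id))
  if (!is.na(hit)) {
    return(list(bk = "exact", place_id = gazetteer$place_id[hit],
                region_id = gazetteer$region[hit]))
  }
  rhit <- match(.norm_place(cell), .norm_place(names(polygons)))
  if (!is.na(rhit)) {
    return(list(bk = "region_only", place_id = NA_character_,
                region_id = names(polygons)[rhit]))
  }
  list(bk = "unresolved", place_id = NA_character_, region_id = NA_character_)
}

#' Read a genealogy table and resolve every birthplace
#'
#' The genealogy table holds one row per proband with the birthplaces of the
#' proband, both parents and all four grandparents.  An empty cell means the
#' birthplace is unknown; a cell naming a region (matched case-insensitively
#' against the polygon region ids) means the birthplace is known only at
#' regional resolution; anything else must be a gazetteer `place_id`.
#'
#' @param table_path genealogy CSV (see Details for the column schema).
#' @param gazetteer_path gazetteer CSV, see [read_gazetteer()].
#' @param polygons_path region polygons GeoJSON, see [read_region_polygons()].
#' @param quiet suppress the row/column count messages.
#' @details Required columns: `family_id, proband_id, sibling_group, sex,
#'   birth_year, birthplace, mother_birthplace, father_birthplace,
#'   mgm_birthplace, mgf_birthplace, pgm_birthplace, pgf_birthplace`.
#'   Additional per-member columns (birth years, ethnicity) are carried
#'   through untouched.
#' @return list with `persons` (one row per family member, with the
#'   birthplace knowledge state in `bk`), `gazetteer` and `polygons`.
#' @export
read_genealogy <- function(table_path, gazetteer_path, polygons_path,
                           quiet = FALSE) {
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  gazetteer <- read_gazetteer(gazetteer_path)
  polygons <- read_region_polygons(polygons_path)
  roles <- kinloc_roles()
  req <- c("family_id", "proband_id", "sibling_group", "sex", "birth_year",
           roles$column)
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("genealogy table lacks columns: ",
                         paste(miss, collapse = ", "))
  dup <- tab$family_id[duplicated(tab$family_id)]
  if (length(dup)) {
    stop("duplicate proband for family: ", paste(unique(dup), collapse = ", "))
  }
  persons <- build_persons(tab, gazetteer, polygons)
  if (!quiet) {
    message(sprintf("read %d families (%d persons), %d gazetteer places, %d regions",
                    nrow(tab), nrow(persons), nrow(gazetteer), length(polygons)))
  }
  list(persons = persons, gazetteer = gazetteer, polygons = polygons)
}

#' Build person records from a genealogy table held in memory
#' @param tab data frame in the genealogy-table schema.
#' @param gazetteer,polygons as returned by the readers.
#' @return data frame of person records.
#' @export
build_persons <- function(tab, gazetteer, polygons) {
  roles <- kinloc_roles()
  recs <- vector("list", nrow(tab) * nrow(roles))
  bad <- character()
  k <- 0L
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(nrow(roles))) {
      cell <- tab[[roles$column[j]]][i]
      res <- .resolve_place(cell, gazetteer, polygons)
      if (res$bk == "unresolved") {
        bad <- c(bad, sprintf("row %d (%s): '%s'", i, roles$role[j], cell))
        next
      }
      byr_col <- if (roles$role[j] == "proband") "birth_year" else
        paste0(roles$role[j], "_birth_year")
      byr <- if (byr_col %in% names(tab)) suppressWarnings(as.numeric(tab[[byr_col]][i])) else NA_real_
      k <- k + 1L
      recs[[k]] <- data.frame(
        person_id = if (roles$role[j] == "proband") tab$proband_id[i] else
          paste(tab$family_id[i], roles$role[j], sep = ":"),
        family_id = tab$family_id[i],
        role = roles$role[j],
        sex = if (roles$role[j] == "proband") tolower(tab$sex[i]) else roles$sex[j],
        generation = roles$generation[j],
        bk = res$bk,
        place_id = res$place_id,
        region_id = res$region_id,
        birth_year = byr,
        sibling_group = if (roles$role[j] == "proband") tab$sibling_group[i] else NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(bad)) {
    stop("birthplaces not found in gazetteer or regions:\n  ",
         paste(bad, collapse = "\n  "))
  }
  do.call(rbind, recs[seq_len(k)])
}

#' Remove sibling probands at random
#'
#' Probands sharing a declared sibling-group identifier would double-count
#' their parents' and grandparents' migrations; exactly one proband per
#' sibling group is retained, chosen by a seeded uniform draw.  Families of
#' dropped probands are removed entirely.
#'
#' @param persons person records (see [read_genealogy()]).
#' @param seed integer seed; the selection is a deterministic function of it.
#' @param quiet suppress the removal-count message.
#' @return person records with at most one proband per sibling group.
#' @export
dedupe_siblings <- function(persons, seed = 1L, quiet = FALSE) {
  pro <- persons[persons$role == "proband", ]
  grp <- pro$sibling_group
  has_grp <- !is.na(grp) & nzchar(grp)
  if (!any(has_grp)) return(persons)
  keep_fam <- pro$family_id[!has_grp]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  for (g in sort(unique(grp[has_grp]))) {
    fams <- sort(pro$family_id[has_grp & grp == g])
    keep_fam <- c(keep_fam, fams[sample.int(length(fams), 1L)])
  }
  dropped <- setdiff(pro$family_id, keep_fam)
  if (!quiet && length(dropped)) {
    message(sprintf("dedupe_siblings: removed %d of %d probands", length(dropped),
                    nrow(pro)))
  }
  persons[persons$family_id %in% keep_fam, , drop = FALSE]
}
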