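# shared fixtures, built in code at test time

# a small simulated study (gazetteer, families, degraded persons, outcomes)
tiny_study <- function(seed = 11, nf = 17, np = 15, degrade_data = TRUE) {
  cfg <- sim_config(seed = seed, n_families_per_region = nf,
                    n_places_per_region = np)
  gz <- simulate_gazetteer(cfg)
  sim <- simulate_families(cfg, gz$gazetteer, gz$polygons)
  obs <- if (degrade_data) degrade(sim, cfg) else sim
  dm <- build_distance_matrix(gz$gazetteer)
  out <- build_migration_outcomes(obs$persons, dm, gz$polygons, gz$gazetteer)
  list(cfg = cfg, gazetteer = gz$gazetteer, polygons = gz$polygons,
       sim = sim, persons = obs$persons, dm = dm, outcomes = out)
}

# hand-built gazetteer of 4 exactly placed equatorial towns + 2 regions
toy_gazetteer <- function() {
  data.frame(
    place_id = c("A", "B", "C", "D"),
    name = c("town A", "town B", "town C", "farm D"),
    lat = c(0, 0, 0, 1),
    lon = c(0, 0.54, 1.08, 0.5),
    region = c("West", "West", "East", "West"),
    settlement_size = c("town", "city", "farm", "farm"),
    stringsAsFactors = FALSE
  )
}

toy_polygons <- function() {
  list(West = data.frame(lat = c(-0.7, -0.7, 1.6, 1.6),
                         lon = c(-0.3, 0.8, 0.8, -0.3)),
       East = data.frame(lat = c(-0.7, -0.7, 1.6, 1.6),
                         lon = c(0.9, 1.4, 1.4, 0.9)))
}

# one family of person records with configurable birthplace cells
toy_family <- function(birthplaces = list()) {
  roles <- kinloc:::kinloc_roles()
  defaults <- list(proband = "A", mother = "A", father = "A",
                   maternal_grandmother = "A", maternal_grandfather = "A",
                   paternal_grandmother = "A", paternal_grandfather = "A")
  defaults[names(birthplaces)] <- birthplaces
  gz <- toy_gazetteer()
  rows <- lapply(seq_len(nrow(roles)), function(j) {
    r <- roles$role[j]
    bp <- defaults[[r]]
    bk <- if (is.na(bp)) "unknown" else if (bp %in% gz$place_id) "exact"
      else "region_only"
    data.frame(person_id = paste0("F1:", r), family_id = "F1", role = r,
               sex = ifelse(r == "proband", "female", roles$sex[j]),
               generation = roles$generation[j], bk = bk,
               place_id = if (bk == "exact") bp else NA_character_,
               region_id = if (bk == "exact")
                 gz$region[match(bp, gz$place_id)] else
                   if (bk == "region_only") bp else NA_character_,
               birth_year = ifelse(r == "proband", 1957, NA_real_),
               sibling_group = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# spherical law of cosines: independent great-circle oracle
slc_km <- function(a, b, R = 6378.137) {
  a <- a * pi / 180; b <- b * pi / 180
  cc <- sin(a[1]) * sin(b[1]) + cos(a[1]) * cos(b[1]) * cos(b[2] - a[2])
  R * acos(pmin(1, pmax(-1, cc)))
}
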