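test_that("residence classification follows the shared-birthplace definitions", {
  expect_equal(classify_residence("A", "A", "A"), "equilocal")
  expect_equal(classify_residence("A", "A", "B"), "matrilocal")
  expect_equal(classify_residence("A", "B", "A"), "patrilocal")
  expect_equal(classify_residence("A", "B", "C"), "neolocal")
  expect_equal(classify_residence("A", NA, "B"), "missing")
  expect_equal(classify_residence("A", "unknown", "A"), "missing")
})

test_that("migration dyads carry the right status, distance and censoring", {
  gz <- toy_gazetteer()
  dm <- build_distance_matrix(gz)
  polys <- toy_polygons()
  # mother born where the proband was born: observed non-migration
  out <- build_migration_outcomes(toy_family(), dm, polys, gz)
  expect_equal(nrow(out), 6)
  mo <- out[out$dyad == "proband-mother", ]
  expect_equal(mo$status, "observed")
  expect_equal(mo$d, 0)
  expect_equal(mo$migrated, "no")
  expect_equal(mo$mover_generation, "parent")
  expect_equal(mo$mover_sex, "female")
  # mother born at B, ~60 km from A: observed migration with that distance
  out2 <- build_migration_outcomes(toy_family(list(mother = "B")), dm, polys, gz)
  mo2 <- out2[out2$dyad == "proband-mother", ]
  expect_equal(mo2$status, "observed")
  expect_equal(mo2$migrated, "yes")
  expect_equal(mo2$d, dm["A", "B"])
  expect_equal(mo2$d, 60, tolerance = 0.01)
  # grandmother known only to come from the mother's own region: the
  # migration indicator stays latent and the interval starts at zero
  out3 <- build_migration_outcomes(toy_family(list(maternal_grandmother = "West")),
                                   dm, polys, gz)
  gm <- out3[out3$dyad == "mother-maternal_grandmother", ]
  expect_equal(gm$status, "status_unknown_censored")
  expect_equal(gm$d_min, 0)
  b <- censoring_bounds(c(gz$lat[1], gz$lon[1]), polys$West)
  expect_equal(gm$d_max, unname(b["d_max"]))
  expect_equal(gm$migrated, "unknown")
  # grandmother from a different region: a known migration, bounded both ways
  out4 <- build_migration_outcomes(toy_family(list(maternal_grandmother = "East")),
                                   dm, polys, gz)
  gm4 <- out4[out4$dyad == "mother-maternal_grandmother", ]
  expect_equal(gm4$status, "interval_censored")
  expect_true(gm4$d_min > 0 && gm4$d_min < gm4$d_max)
  expect_equal(gm4$migrated, "yes")
  # unknown endpoints drop the dyad
  out5 <- build_migration_outcomes(toy_family(list(father = NA)), dm, polys, gz)
  expect_equal(out5$status[out5$dyad == "proband-father"], "missing")
})

test_that("censored dyads never invert their interval", {
  st <- tiny_study(seed = 31, nf = 25, np = 10)
  cz <- st$outcomes[st$outcomes$status %in%
                      c("interval_censored", "status_unknown_censored"), ]
  expect_gt(nrow(cz), 0)
  expect_true(all(cz$d_min <= cz$d_max))
  expect_true(all(cz$d_min[cz$status == "status_unknown_censored"] == 0))
  expect_true(all(cz$d_min[cz$status == "interval_censored"] > 0))
})

test_that("residence outcomes per family follow birthplace availability", {
  gz <- toy_gazetteer()
  ro <- build_residence_outcomes(toy_family(), gz)
  expect_equal(nrow(ro), 3)
  expect_equal(unname(table(ro$type)[["equilocal"]]), 3)
  # no paternal grandparent birthplaces: the father-side couple is missing
  ro2 <- build_residence_outcomes(
    toy_family(list(paternal_grandmother = NA, paternal_grandfather = NA)), gz)
  expect_equal(ro2$type[grepl("paternal", ro2$couple_id)], "missing")
  expect_equal(sum(ro2$type != "missing"), 2)
  ro3 <- build_residence_outcomes(
    toy_family(list(proband = "C", mother = "A", father = "B")), gz)
  expect_equal(ro3$type[grepl(":parents", ro3$couple_id)], "neolocal")
})

test_that("outcome summaries count movers and order statistics correctly", {
  mk <- function(d) data.frame(
    region = "West", mover_generation = "parent", mover_sex = "female",
    status = "observed", d = d, stringsAsFactors = FALSE)
  s <- summarize_outcomes(migration = mk(c(rep(0, 70), rep(10, 30))))
  expect_equal(s$overall$prop_migrated, 0.3)
  s2 <- summarize_outcomes(migration = mk(c(0, 10, 20, 30)))
  expect_equal(s2$overall$median_km, 20)
  expect_equal(s2$overall$iqr_km, 10)
  s3 <- summarize_outcomes(migration = mk(rep(0, 5)))
  expect_equal(s3$overall$prop_migrated, 0)
  expect_true(is.na(s3$overall$median_km))
})
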