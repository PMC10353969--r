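test_that("haversine distance has the right identities and closed forms", {
  expect_equal(haversine_km(c(12.3, 45.6), c(12.3, 45.6)), 0)
  # antipodal points on the equator are half a great circle apart
  expect_equal(haversine_km(c(0, 0), c(0, 180)),
               pi * kinloc_earth_radius_km(), tolerance = 1e-10)
  a <- c(-32.1, 18.9); b <- c(-28.6, 17.2)
  expect_equal(haversine_km(a, b), haversine_km(b, a))
  expect_error(haversine_km(c(95, 0), c(0, 0)), "out of range")
})

test_that("haversine agrees with a spherical-law-of-cosines oracle", {
  set.seed(401)
  n <- 1000
  a <- cbind(runif(n, -80, 80), runif(n, -179, 179))
  b <- cbind(runif(n, -80, 80), runif(n, -179, 179))
  d <- haversine_km(a, b)
  o <- vapply(seq_len(n), function(i) slc_km(a[i, ], b[i, ]), numeric(1))
  keep <- d < 19000   # law of cosines loses precision near the antipode
  expect_lt(max(abs(d[keep] - o[keep])), 1e-6)
})

test_that("distance matrices are symmetric, zero-diagonal and additive on a geodesic", {
  g1 <- data.frame(place_id = "X", lat = 5, lon = 5)
  expect_equal(unname(build_distance_matrix(g1)[1, 1]), 0)
  # collinear equatorial places: great-circle distances add exactly
  g3 <- data.frame(place_id = c("P0", "P1", "P2"), lat = 0, lon = c(0, 1, 2))
  d3 <- build_distance_matrix(g3)
  expect_equal(d3["P0", "P2"], d3["P0", "P1"] + d3["P1", "P2"],
               tolerance = 1e-9 / d3["P0", "P2"])
  set.seed(402)
  for (rep in 1:5) {
    g <- data.frame(place_id = paste0("p", 1:10),
                    lat = runif(10, -60, 60), lon = runif(10, -170, 170))
    d <- build_distance_matrix(g)
    expect_identical(unname(diag(d)), rep(0, 10))
    expect_identical(d, t(d) * 1)
    expect_true(all(d >= 0) && all(d <= pi * kinloc_earth_radius_km()))
  }
})

test_that("censoring bounds behave for interior and exterior anchors", {
  poly <- data.frame(lat = c(-0.5, -0.5, 0.5, 0.5), lon = c(-0.5, 0.5, 0.5, -0.5))
  inb <- censoring_bounds(c(0, 0), poly)
  expect_equal(unname(inb["d_min"]), 0)
  expect_gt(inb["d_max"], 0)
  outb <- censoring_bounds(c(0, 3), poly)
  expect_gt(outb["d_min"], 0)
  expect_gt(outb["d_max"], outb["d_min"])
  expect_error(censoring_bounds(c(0, 0), poly[1:2, ]), "degenerate")
})

test_that("censoring bounds match a dense grid-search oracle", {
  # 1x1 degree equatorial square, external point due east of the nearest edge
  poly <- data.frame(lat = c(-0.5, -0.5, 0.5, 0.5), lon = c(0, 1, 1, 0))
  p <- c(0, 2.5)
  b <- censoring_bounds(p, poly)
  gs <- seq(-0.5, 0.5, by = 0.004)
  lon <- seq(0, 1, by = 0.004)
  grid <- as.matrix(expand.grid(lat = gs, lon = lon))
  dg <- haversine_km(matrix(rep(p, nrow(grid)), ncol = 2, byrow = TRUE), grid)
  expect_lt(abs(b["d_min"] - min(dg)), 0.5)
  expect_lt(abs(b["d_max"] - max(dg)), 0.5)
})

test_that("enlarging the region never tightens the censoring bounds", {
  set.seed(403)
  for (rep in 1:10) {
    ctr <- c(runif(1, -40, 40), runif(1, -40, 40))
    half <- runif(1, 0.2, 0.8)
    small <- data.frame(lat = ctr[1] + half * c(-1, -1, 1, 1),
                        lon = ctr[2] + half * c(-1, 1, 1, -1))
    big <- data.frame(lat = ctr[1] + 2 * half * c(-1, -1, 1, 1),
                      lon = ctr[2] + 2 * half * c(-1, 1, 1, -1))
    p <- ctr + runif(2, -3, 3)
    bs <- censoring_bounds(p, small, max_seg_km = 2)
    bb <- censoring_bounds(p, big, max_seg_km = 2)
    expect_lte(bb["d_min"], bs["d_min"] + 1e-9)
    expect_gte(bb["d_max"], bs["d_max"] - 1e-9)
  }
})
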