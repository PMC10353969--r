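#' Great-circle distance between two points
#'
#' Haversine great-circle distance in kilometres between coordinate pairs
#' given as `(lat, lon)` in decimal degrees.  The computation is delegated to
#' [geosphere::distHaversine()]; the sphere radius defaults to the WGS-84
#' equatorial radius expressed in kilometres.
#'
#' @param a,b numeric vectors `c(lat, lon)` in degrees, or two-column
#'   matrices (one point per row, columns lat then lon).
#' @param radius_km sphere radius in kilometres.
#' @return distance(s) in kilometres.
#' @export
haversine_km <- function(a, b, radius_km = kinloc_earth_radius_km()) {
  a <- .coord_matrix(a)
  b <- .coord_matrix(b)
  .check_coords(a)
  .check_coords(b)
  # geosphere expects (lon, lat)
  geosphere::distHaversine(a[, 2:1, drop = FALSE], b[, 2:1, drop = FALSE],
                           r = radius_km)
}

#' Earth radius used for all distances
#'
#' Returns the sphere radius in kilometres used by the package (the WGS-84
#' equatorial radius, matching the default of the geosphere distance
#' routines).  Override via `options(kinloc.earth_radius_km = ...)`.
#' @return radius in kilometres.
#' @export
kinloc_earth_radius_km <- function() {
  getOption("kinloc.earth_radius_km", 6378.137)
}

.coord_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 2, byrow = TRUE) else as.matrix(x)
}

.check_coords <- function(m) {
  if (anyNA(m) || any(m[, 1] < -90 | m[, 1] > 90) ||
      any(m[, 2] < -180 | m[, 2] > 180)) {
    stop("coordinates out of range: lat must lie in [-90, 90], lon in [-180, 180]")
  }
  invisible(m)
}

#' Pairwise distance matrix for a gazetteer
#'
#' @param gazetteer data frame with columns `place_id`, `lat`, `lon`.
#' @param radius_km sphere radius in kilometres.
#' @return object of class `kinloc_distmatrix`: a symmetric, zero-diagonal
#'   matrix of great-circle distances (km) with `place_id` dimnames.
#' @export
build_distance_matrix <- function(gazetteer, radius_km = kinloc_earth_radius_km()) {
  stopifnot(all(c("place_id", "lat", "lon") %in% names(gazetteer)))
  if (anyDuplicated(gazetteer$place_id)) {
    stop("duplicate place_id in gazetteer")
  }
  pts <- cbind(gazetteer$lon, gazetteer$lat)
  .check_coords(cbind(gazetteer$lat, gazetteer$lon))
  n <- nrow(pts)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- geosphere::distHaversine(pts[i, , drop = FALSE], pts,
                                       r = radius_km)
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(gazetteer$place_id, gazetteer$place_id)
  class(d) <- c("kinloc_distmatrix", class(d))
  d
}

#' Densify a polygon ring along great circles
#'
#' Inserts intermediate points on every edge so that no segment is longer
#' than `max_seg_km`.  Used to evaluate point-to-region distances on the
#' sphere; for the small study regions involved the densification error is
#' far below reporting precision.
#'
#' @param ring matrix with columns `lat`, `lon` (closed or open ring).
#' @param max_seg_km maximum segment length in km.
#' @return matrix of `(lat, lon)` boundary points.
#' @keywords internal
densify_ring <- function(ring, max_seg_km = 0.5) {
  ring <- as.matrix(ring[, c("lat", "lon"), drop = FALSE])
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  n <- nrow(ring)
  if (n < 3) stop("degenerate polygon: fewer than 3 distinct vertices")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p1 <- ring[i, ]
    p2 <- ring[if (i == n) 1L else i + 1L, ]
    len <- haversine_km(p1, p2)
    if (len <= max_seg_km) {
      out[[i]] <- matrix(p1, ncol = 2)
    } else {
      k <- ceiling(len / max_seg_km) - 1L
      mid <- geosphere::gcIntermediate(rev(p1), rev(p2), n = k,
                                       addStartEnd = FALSE)
      out[[i]] <- rbind(p1, mid[, 2:1, drop = FALSE])
    }
  }
  pts <- do.call(rbind, out)
  colnames(pts) <- c("lat", "lon")
  pts
}

#' Censoring bounds between a fixed place and a region polygon
#'
#' For a person whose exact birthplace is unknown but whose natal region is
#' known, the migration distance relative to a fixed anchor birthplace is
#' bounded below by the nearest point of the region and above by the
#' farthest point.  If the anchor lies inside (or on) the region the lower
#' bound is zero.  Distances are great-circle distances to the region
#' boundary, densified to short segments.
#'
#' @param fixed_place a list/row with `lat` and `lon` (degrees), or
#'   `c(lat, lon)`.
#' @param region polygon ring: matrix or data frame with columns `lat`,
#'   `lon` (at least 3 distinct vertices).
#' @param max_seg_km densification step for the boundary (km).
#' @param boundary optional precomputed densified boundary (from
#'   [densify_ring()]); avoids re-densifying when many anchors share a
#'   region.
#' @return named numeric `c(d_min, d_max)` in kilometres.
#' @export
censoring_bounds <- function(fixed_place, region, max_seg_km = 0.5,
                             boundary = NULL) {
  p <- if (is.list(fixed_place) && !is.data.frame(fixed_place)) {
    c(fixed_place$lat, fixed_place$lon)
  } else if (is.data.frame(fixed_place)) {
    c(fixed_place$lat[1], fixed_place$lon[1])
  } else {
    fixed_place
  }
  .check_coords(matrix(p, ncol = 2))
  bnd <- if (is.null(boundary)) densify_ring(region, max_seg_km = max_seg_km)
    else boundary
  d <- haversine_km(matrix(rep(p, nrow(bnd)), ncol = 2, byrow = TRUE), bnd)
  ring <- as.matrix(region[, c("lat", "lon"), drop = FALSE])
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  inside <- mgcv::in.out(cbind(ring[, 2], ring[, 1]),
                         matrix(c(p[2], p[1]), ncol = 2))
  d_min <- if (isTRUE(inside[1]) || min(d) < 1e-9) 0 else min(d)
  c(d_min = d_min, d_max = max(d))
}
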