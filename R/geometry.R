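# Planar polygon primitives. Synthetic regions live on a flat km grid so all
# geometry here is Euclidean; geodesic variants for real lon/lat data are
# provided through the `distance_mode` arguments of the classifiers.

#' Signed area of a polygon ring (shoelace formula)
#' @param ring A numeric matrix with columns x, y; the ring may be open or
#'   closed (first vertex repeated).
#' @return Signed area; positive for counterclockwise rings.
#' @keywords internal
ring_signed_area <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

close_ring <- function(ring) {
  if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 3) {
    abort("polygon rings must be numeric matrices with two columns and >= 3 vertices.")
  }
  if (any(!is.finite(ring))) abort("polygon ring contains non-finite coordinates.")
  if (ring[1, 1] != ring[nrow(ring), 1] || ring[1, 2] != ring[nrow(ring), 2]) {
    ring <- rbind(ring, ring[1, ])
  }
  ring
}

#' Area centroid of a polygon ring
#' @inheritParams ring_signed_area
#' @return Numeric vector `c(x, y)`.
#' @keywords internal
ring_centroid <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  cross <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(c(mean(x[-n]), mean(y[-n])))
  cx <- sum((x[-n] + x[-1]) * cross) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cross) / (6 * a)
  c(cx, cy)
}

# Even-odd ray-cast point-in-polygon test (boundary counts as inside only by
# luck of floating point; callers that care use point_ring_distance == 0).
point_in_ring <- function(px, py, ring) {
  ring <- close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring) - 1L
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((y[i] > py) != (y[j] > py)) &&
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else ((px - x1) * dx + (py - y1) * dy) / len2
  t <- min(1, max(0, t))
  qx <- x1 + t * dx; qy <- y1 + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

#' Distance from a point to a polygon (zero when inside)
#' @param px,py Point coordinates.
#' @param ring Polygon ring matrix.
#' @return Non-negative distance in the coordinate units.
#' @keywords internal
point_ring_distance <- function(px, py, ring) {
  ring <- close_ring(ring)
  if (point_in_ring(px, py, ring)) return(0)
  n <- nrow(ring)
  dmin <- Inf
  for (i in seq_len(n - 1L)) {
    d <- point_segment_distance(px, py, ring[i, 1], ring[i, 2],
                                ring[i + 1L, 1], ring[i + 1L, 2])
    if (d < dmin) dmin <- d
  }
  dmin
}

#' Distances from one point to many block-group polygons
#' @param px,py Point coordinates.
#' @param geometry List of polygon ring matrices.
#' @return Numeric vector of distances.
#' @keywords internal
point_polys_distance <- function(px, py, geometry) {
  vapply(geometry, function(g) point_ring_distance(px, py, g), numeric(1))
}

#' Bearing from one point to another, mathematical convention
#'
#' Degrees counterclockwise from east (the +x axis), in `[0, 360)` — the same
#' convention as [leeward_angle()], so downwind comparisons are internally
#' consistent.
#'
#' @param from_x,from_y,to_x,to_y Coordinates.
#' @return Bearing in degrees.
#' @export
bearing_deg <- function(from_x, from_y, to_x, to_y) {
  (atan2(to_y - from_y, to_x - from_x) * 180 / pi) %% 360
}

# Geodesic counterparts (lon/lat degrees, WGS84) for real-data mode. geosphere
# returns compass bearings (clockwise from north); convert to the package's
# math convention.
geo_point_polys_distance <- function(px, py, geometry) {
  if (!requireNamespace("geosphere", quietly = TRUE)) {
    abort("geodesic mode requires the 'geosphere' package.")
  }
  vapply(geometry, function(g) {
    g <- close_ring(g)
    min(geosphere::distGeo(c(px, py), g)) / 1000
  }, numeric(1))
}

geo_bearing_deg <- function(from_x, from_y, to_x, to_y) {
  if (!requireNamespace("geosphere", quietly = TRUE)) {
    abort("geodesic mode requires the 'geosphere' package.")
  }
  b <- geosphere::bearing(cbind(from_x, from_y), cbind(to_x, to_y))
  (90 - b) %% 360
}
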