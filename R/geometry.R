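# Internal planar geometry. All coordinates are projected metres; no
# geographic handling here (reprojection is upstream of this package).

#' Cumulative arc length of a polyline
#'
#' @param coords two-column matrix of vertex coordinates (m).
#' @return numeric vector, length `nrow(coords)`, starting at 0 (m).
#' @keywords internal
#' @noRd
arc_length <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 2)
  if (nrow(coords) < 2L) return(rep(0, nrow(coords)))
  seg <- sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2)
  c(0, cumsum(seg))
}

#' Interpolate points at given arc-length positions along a polyline
#'
#' @param coords vertex matrix; `s` arc positions (m), all within total length.
#' @return matrix of interpolated coordinates.
#' @keywords internal
#' @noRd
interp_along <- function(coords, s) {
  cum <- arc_length(coords)
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  # segment index for each s: last vertex with cum <= s (capped at n-1)
  idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(coords) - 1L)
  seg_len <- cum[idx + 1L] - cum[idx]
  frac <- ifelse(seg_len > 0, (s - cum[idx]) / seg_len, 0)
  cbind(
    coords[idx, 1] + frac * (coords[idx + 1L, 1] - coords[idx, 1]),
    coords[idx, 2] + frac * (coords[idx + 1L, 2] - coords[idx, 2])
  )
}

#' Ray-casting point-in-polygon test, boundary-inclusive
#'
#' A point lying on a polygon edge (within `eps` metres) counts as inside;
#' callers that need a deterministic tie-break across polygons sharing a
#' boundary resolve it by visiting polygons in a fixed order.
#'
#' @param px,py point coordinates (vectors).
#' @param ring two-column matrix, closed or open ring (closure not required).
#' @return logical vector.
#' @keywords internal
#' @noRd
point_in_ring <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring)
  if (n >= 3L && all(ring[1, ] == ring[n, ])) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    # boundary check: distance from point to segment (i,j)
    d <- dist_point_segment(px, py, xi, yi, xj, yj)
    on_edge <- on_edge | d <= eps
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | on_edge
}

#' Distance from points to one segment
#' @keywords internal
#' @noRd
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Minimum distance from points to a polygon (0 if inside)
#'
#' @param px,py point coordinate vectors; `ring` polygon ring matrix.
#' @return numeric vector of distances (m).
#' @keywords internal
#' @noRd
dist_point_ring <- function(px, py, ring) {
  n <- nrow(ring)
  if (n >= 3L && all(ring[1, ] == ring[n, ])) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1L
  }
  d <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    d <- pmin(d, dist_point_segment(px, py,
                                    ring[j, 1], ring[j, 2],
                                    ring[i, 1], ring[i, 2]))
    j <- i
  }
  d[point_in_ring(px, py, ring)] <- 0
  d
}
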