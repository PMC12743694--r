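# Plain planar geometry on matrices of (x, y) vertices. All coordinates are in
# the shared projected metric CRS; no ellipsoidal maths anywhere.

#' Test points against a polygon
#'
#' Ray-casting point-in-polygon test, vectorised over points. Points exactly on
#' an edge may fall on either side at floating-point precision; callers that
#' care about the boundary should test distance to the boundary instead.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param poly Two-column matrix of polygon vertices (open ring; the closing
#'   edge back to the first vertex is implied).
#' @return Logical vector, `TRUE` where the point lies inside.
#' @export
pts_in_polygon <- function(px, py, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Distance from points to a segment
#'
#' @param px,py Point coordinates (vectorised).
#' @param ax,ay,bx,by Segment endpoints.
#' @return Numeric vector of Euclidean distances.
#' @export
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

orient2 <- function(ax, ay, bx, by, cx, cy) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  sign(v)
}

on_segment <- function(ax, ay, bx, by, px, py) {
  px >= pmin(ax, bx) - 1e-12 & px <= pmax(ax, bx) + 1e-12 &
    py >= pmin(ay, by) - 1e-12 & py <= pmax(ay, by) + 1e-12
}

#' Do two segments intersect?
#'
#' Proper intersections and collinear touching both count.
#'
#' @param a1,a2,b1,b2 Length-2 numeric vectors (x, y): endpoints of segments
#'   `a1--a2` and `b1--b2`.
#' @return `TRUE` if the closed segments share at least one point.
#' @export
segments_intersect <- function(a1, a2, b1, b2) {
  d1 <- orient2(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])
  d2 <- orient2(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])
  d3 <- orient2(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])
  d4 <- orient2(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2])
  if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(TRUE)
  if (d1 == 0 && on_segment(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])) return(TRUE)
  if (d2 == 0 && on_segment(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])) return(TRUE)
  if (d3 == 0 && on_segment(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])) return(TRUE)
  if (d4 == 0 && on_segment(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2])) return(TRUE)
  FALSE
}

#' Minimum distance between two segments
#'
#' @inheritParams segments_intersect
#' @return 0 if the segments intersect, otherwise the minimum of the four
#'   endpoint-to-segment distances.
#' @export
dist_segment_segment <- function(a1, a2, b1, b2) {
  if (segments_intersect(a1, a2, b1, b2)) return(0)
  min(dist_point_segment(a1[1], a1[2], b1[1], b1[2], b2[1], b2[2]),
      dist_point_segment(a2[1], a2[2], b1[1], b1[2], b2[1], b2[2]),
      dist_point_segment(b1[1], b1[2], a1[1], a1[2], a2[1], a2[2]),
      dist_point_segment(b2[1], b2[2], a1[1], a1[2], a2[1], a2[2]))
}

poly_edges <- function(poly) {
  n <- nrow(poly)
  cbind(poly, poly[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2 per row
}

#' Boundary-to-boundary distance between two simple polygons
#'
#' Minimum Euclidean distance between the polygon boundaries; 0 when they
#' touch, cross, or one contains the other.
#'
#' @param p1,p2 Two-column vertex matrices.
#' @return Distance in map units.
#' @export
dist_polygon_polygon <- function(p1, p2) {
  if (any(pts_in_polygon(p2[, 1], p2[, 2], p1)) ||
      any(pts_in_polygon(p1[, 1], p1[, 2], p2))) return(0)
  e1 <- poly_edges(p1); e2 <- poly_edges(p2)
  best <- Inf
  for (i in seq_len(nrow(e1))) {
    a1 <- e1[i, 1:2]; a2 <- e1[i, 3:4]
    for (j in seq_len(nrow(e2))) {
      d <- dist_segment_segment(a1, a2, e2[j, 1:2], e2[j, 3:4])
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  }
  best
}

#' Distance from a point to a polygon boundary
#'
#' @param px,py Point coordinates (vectorised).
#' @param poly Two-column vertex matrix.
#' @return Numeric vector of distances to the nearest boundary point
#'   (regardless of whether the point is inside).
#' @export
dist_point_polygon_boundary <- function(px, py, poly) {
  e <- poly_edges(poly)
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(e))) {
    d <- pmin(d, dist_point_segment(px, py, e[i, 1], e[i, 2], e[i, 3], e[i, 4]))
  }
  d
}

#' Distance from a point to a polyline
#'
#' @param px,py Point coordinates (vectorised).
#' @param line Two-column vertex matrix of an open polyline.
#' @return Numeric vector of distances.
#' @export
dist_point_polyline <- function(px, py, line) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(line) - 1)) {
    d <- pmin(d, dist_point_segment(px, py, line[i, 1], line[i, 2],
                                    line[i + 1, 1], line[i + 1, 2]))
  }
  d
}

#' Polygon area (shoelace)
#'
#' @param poly Two-column vertex matrix.
#' @return Absolute area in squared map units.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Does a polygon intersect a polyline?
#'
#' `TRUE` if any polyline vertex lies inside the polygon or any polyline
#' segment meets the polygon boundary (overlap, crossing and containment are
#' all subsumed).
#'
#' @param poly Two-column vertex matrix.
#' @param line Two-column polyline vertex matrix.
#' @return Logical scalar.
#' @export
polygon_intersects_polyline <- function(poly, line) {
  if (any(pts_in_polygon(line[, 1], line[, 2], poly))) return(TRUE)
  e <- poly_edges(poly)
  for (i in seq_len(nrow(line) - 1)) {
    s1 <- line[i, ]; s2 <- line[i + 1, ]
    for (j in seq_len(nrow(e))) {
      if (segments_intersect(s1, s2, e[j, 1:2], e[j, 3:4])) return(TRUE)
    }
  }
  FALSE
}

polygons_intersect <- function(p1, p2) {
  if (any(pts_in_polygon(p2[, 1], p2[, 2], p1)) ||
      any(pts_in_polygon(p1[, 1], p1[, 2], p2))) return(TRUE)
  e1 <- poly_edges(p1); e2 <- poly_edges(p2)
  for (i in seq_len(nrow(e1))) {
    for (j in seq_len(nrow(e2))) {
      if (segments_intersect(e1[i, 1:2], e1[i, 3:4], e2[j, 1:2], e2[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

rect_polygon <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}
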