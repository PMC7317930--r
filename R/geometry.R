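# Planar geometry primitives for profile polygons and particle coordinates.
# All coordinates are in nanometres, origin top-left, y pointing down,
# continuous (never pixel-snapped). Polygons are simple closed rings stored
# as an n x 2 matrix of vertices (first vertex NOT repeated at the end).

#' Signed polygon area by the shoelace formula
#'
#' @param ring numeric matrix with columns x, y (nm); vertices of a simple
#'   polygon, first vertex not repeated.
#' @return Signed area in nm^2 (positive for counter-clockwise rings in a
#'   y-down frame this is clockwise on screen; callers normally take `abs`).
#' @keywords internal
shoelace_area <- function(ring) {
  n <- nrow(ring)
  if (is.null(n) || n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Polygon area in square micrometres
#' @param ring vertex matrix in nm.
#' @return area in um^2.
#' @export
polygon_area_um2 <- function(ring) abs(shoelace_area(ring)) / 1e6

#' Test points against a polygon by the nonzero winding rule
#'
#' Points within `eps` nm of an edge are counted as inside, so boundary
#' particles are assigned to the containing profile rather than lost to
#' floating-point jitter.
#'
#' @param x,y point coordinates (nm).
#' @param ring polygon vertex matrix (nm).
#' @param eps boundary tolerance in nm (default 1).
#' @return logical vector, TRUE when the point is inside or on the boundary.
#' @export
point_in_polygon <- function(x, y, ring, eps = 1) {
  n <- nrow(ring)
  px <- ring[, 1]; py <- ring[, 2]
  qx <- px[c(2:n, 1)]; qy <- py[c(2:n, 1)]
  inside <- logical(length(x))
  for (i in seq_along(x)) {
    wn <- 0L
    # winding number accumulation over directed edges (p -> q)
    up <- py <= y[i]
    left <- (qx - px) * (y[i] - py) - (x[i] - px) * (qy - py)
    wn <- sum(up & (qy > y[i]) & (left > 0)) - sum(!up & (qy <= y[i]) & (left < 0))
    if (wn != 0L) { inside[i] <- TRUE; next }
    if (eps > 0 && dist_to_ring(x[i], y[i], ring) <= eps) inside[i] <- TRUE
  }
  inside
}

#' Minimum distance from a point to a polygon boundary
#' @keywords internal
dist_to_ring <- function(x, y, ring) {
  n <- nrow(ring)
  px <- ring[, 1]; py <- ring[, 2]
  qx <- px[c(2:n, 1)]; qy <- py[c(2:n, 1)]
  min(point_segment_distance(x, y, px, py, qx, qy))
}

#' Distance from one point to each of a set of segments
#'
#' Vectorized over segments; used for membrane-contour classification where
#' the contour is an open polyline.
#' @param x,y the point (scalars, nm).
#' @param ax,ay,bx,by segment endpoints (vectors, nm).
#' @return numeric vector of perpendicular (clamped) distances.
#' @keywords internal
point_segment_distance <- function(x, y, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  t <- ifelse(l2 == 0, 0, ((x - ax) * dx + (y - ay) * dy) / l2)
  t <- pmin(1, pmax(0, t))
  cx <- ax + t * dx; cy <- ay + t * dy
  sqrt((x - cx)^2 + (y - cy)^2)
}

#' Distance from points to an open polyline
#' @param x,y point coordinate vectors (nm).
#' @param contour m x 2 vertex matrix of the polyline (nm).
#' @return numeric vector of distances, one per point.
#' @export
dist_to_polyline <- function(x, y, contour) {
  m <- nrow(contour)
  stopifnot(m >= 2)
  ax <- contour[-m, 1]; ay <- contour[-m, 2]
  bx <- contour[-1, 1]; by <- contour[-1, 2]
  vapply(seq_along(x), function(i) {
    min(point_segment_distance(x[i], y[i], ax, ay, bx, by))
  }, numeric(1))
}

#' Uniform random points inside a polygon (bounding-box rejection)
#' @keywords internal
runif_in_polygon <- function(n, ring) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  bx <- range(ring[, 1]); by <- range(ring[, 2])
  out_x <- numeric(0); out_y <- numeric(0)
  # acceptance rate = polygon area / bbox area; draw in batches
  p_acc <- max(abs(shoelace_area(ring)) / (diff(bx) * diff(by)), 0.05)
  while (length(out_x) < n) {
    m <- ceiling((n - length(out_x)) / p_acc) + 16L
    cx <- runif(m, bx[1], bx[2]); cy <- runif(m, by[1], by[2])
    keep <- point_in_polygon(cx, cy, ring, eps = 0)
    out_x <- c(out_x, cx[keep]); out_y <- c(out_y, cy[keep])
  }
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

#' Check that a ring is a simple (non-self-intersecting) polygon
#'
#' O(n^2) segment intersection test; profile rings are small (tens of
#' vertices) so this is cheap.
#' @param ring vertex matrix (nm).
#' @return TRUE/FALSE.
#' @export
is_simple_polygon <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  seg <- function(i) rbind(ring[i, ], ring[if (i == n) 1L else i + 1L, ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  inter <- function(s1, s2) {
    d1 <- cross(s2[1, ], s2[2, ], s1[1, ]); d2 <- cross(s2[1, ], s2[2, ], s1[2, ])
    d3 <- cross(s1[1, ], s1[2, ], s2[1, ]); d4 <- cross(s1[1, ], s1[2, ], s2[2, ])
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) && ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) next
      if (inter(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

#' Convex hull area of a point set
#'
#' Hull vertices from [grDevices::chull()]; area by the shoelace formula.
#' Collinear point sets have zero hull area.
#'
#' @param xy n x 2 coordinate matrix (nm), n >= 3.
#' @return hull area in nm^2.
#' @export
hull_area <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) stop("hull_area() needs at least 3 points")
  h <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(h) < 3) return(0)
  abs(shoelace_area(xy[h, , drop = FALSE]))
}
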