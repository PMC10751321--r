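# Planar polygon primitives used by the geometry generator and the mesher.
# Polygons are closed n x 2 matrices (first vertex NOT repeated at the end);
# all coordinates in mm.

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param poly n x 2 matrix of vertices, closed implicitly.
#' @return signed area in mm^2.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon centroid
#'
#' Area-weighted centroid of a simple polygon.
#'
#' @param poly n x 2 matrix of vertices.
#' @return length-2 numeric vector.
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Test points for inclusion in a polygon
#'
#' Even-odd ray casting, vectorized over query points. Points lying exactly on
#' an edge are classified by the ray parity and should not be relied upon;
#' callers keep query points off boundaries.
#'
#' @param pts m x 2 matrix of query points.
#' @param poly n x 2 polygon.
#' @return logical vector of length m.
#' @export
point_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Segment arrays for a closed polygon: list(a = n x 2 starts, b = n x 2 ends).
poly_segments <- function(poly) {
  list(a = poly, b = poly[c(seq_len(nrow(poly))[-1], 1), , drop = FALSE])
}

# Minimum distance from each point to a set of segments (vectorized).
points_segments_dist <- function(pts, seg) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  m <- nrow(pts); n <- nrow(seg$a)
  ax <- rep(seg$a[, 1], each = m); ay <- rep(seg$a[, 2], each = m)
  bx <- rep(seg$b[, 1], each = m); by <- rep(seg$b[, 2], each = m)
  px <- rep(pts[, 1], n); py <- rep(pts[, 2], n)
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / pmax(L2, 1e-300)))
  qx <- ax + t * dx; qy <- ay + t * dy
  d2 <- (px - qx)^2 + (py - qy)^2
  sqrt(apply(matrix(d2, nrow = m), 1, min))
}

#' Minimum distance between two polygon boundaries
#'
#' For disjoint simple polygons the minimum boundary distance is attained at a
#' vertex of one polygon against an edge of the other, so both directed
#' vertex-to-edge distances are taken.
#'
#' @param poly1,poly2 n x 2 polygons.
#' @return distance in mm.
#' @export
polygon_distance <- function(poly1, poly2) {
  min(points_segments_dist(poly1, poly_segments(poly2)),
      points_segments_dist(poly2, poly_segments(poly1)))
}

# Do two segment sets properly intersect anywhere? Shared endpoints between
# consecutive edges of the same polygon are excluded by the caller.
segments_cross <- function(a1, b1, a2, b2) {
  d <- function(p, q, r) (q[, 1] - p[, 1]) * (r[, 2] - p[, 2]) -
    (q[, 2] - p[, 2]) * (r[, 1] - p[, 1])
  d1 <- d(a2, b2, a1); d2 <- d(a2, b2, b1)
  d3 <- d(a1, b1, a2); d4 <- d(a1, b1, b2)
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
     ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' All non-adjacent edge pairs are checked for proper crossings.
#'
#' @param poly n x 2 polygon.
#' @return logical.
#' @export
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  seg <- poly_segments(poly)
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    j > i + 1 & !(i == 1 & j == n)
  }), arr.ind = TRUE)
  if (nrow(idx) == 0) return(TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  !any(segments_cross(seg$a[i, , drop = FALSE], seg$b[i, , drop = FALSE],
                      seg$a[j, , drop = FALSE], seg$b[j, , drop = FALSE]))
}

# TRUE if polygons' boundaries cross each other anywhere.
polygons_cross <- function(p1, p2) {
  s1 <- poly_segments(p1); s2 <- poly_segments(p2)
  n1 <- nrow(p1); n2 <- nrow(p2)
  i <- rep(seq_len(n1), n2); j <- rep(seq_len(n2), each = n1)
  any(segments_cross(s1$a[i, , drop = FALSE], s1$b[i, , drop = FALSE],
                     s2$a[j, , drop = FALSE], s2$b[j, , drop = FALSE]))
}

# Polygon fully inside another (no boundary crossing, all vertices inside).
polygon_inside <- function(inner, outer) {
  all(point_in_polygon(inner, outer)) && !polygons_cross(inner, outer)
}

# Subdivide polygon edges so that no segment exceeds `h`; original vertices
# are preserved, so the polygonal geometry is unchanged.
polygon_subdivide <- function(poly, h) {
  n <- nrow(poly)
  out <- vector("list", n)
  nxt <- c(seq_len(n)[-1], 1)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[nxt[i], ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / h))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

# Arc-length parametrized ellipse polygon.
ellipse_polygon <- function(center, semi_axes, rotation, spacing) {
  per <- pi * (3 * sum(semi_axes) -
                 sqrt((3 * semi_axes[1] + semi_axes[2]) *
                        (semi_axes[1] + 3 * semi_axes[2])))  # Ramanujan
  n <- max(24L, ceiling(per / spacing))
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- semi_axes[1] * cos(t); y <- semi_axes[2] * sin(t)
  cs <- cos(rotation); sn <- sin(rotation)
  cbind(center[1] + cs * x - sn * y, center[2] + sn * x + cs * y)
}
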