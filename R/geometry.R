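#' 2-D geometry kernel
#'
#' Small, dependency-free planar geometry routines used throughout the
#' package: convex hull area (Graham scan + shoelace), point-in-polygon
#' (ray casting with explicit boundary handling), point-to-segment distance,
#' and the axial angle between an electrode pair and a muscle line.
#'
#' All coordinates are millimetres. Points are length-2 numeric vectors
#' `c(u, v)`; point sets and polygons are n x 2 numeric matrices (columns
#' u, v). Polygons are simple and implicitly closed.
#'
#' @name geometry
#' @keywords internal
NULL

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("u", "v")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  storage.mode(points) <- "double"
  if (ncol(points) != 2 || anyNA(points) || any(!is.finite(points))) {
    rlang::abort("points must be finite n x 2 coordinates", class = "sensorlayout_geometry_error")
  }
  points
}

#' Area of the convex hull of a point set
#'
#' Computes the convex hull by a Graham scan (lowest point pivot, polar-angle
#' sort, counter-clockwise turns) and returns its area via the shoelace
#' formula.
#'
#' @param points an n x 2 numeric matrix or a data frame with columns `u`,
#'   `v`, in mm. At least 3 non-collinear points are required.
#' @return Hull area in mm^2 (non-negative scalar).
#' @export
#' @examples
#' convex_hull_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
convex_hull_area <- function(points) {
  pts <- as_point_matrix(points)
  hull <- graham_scan(pts)
  if (nrow(hull) < 3) {
    rlang::abort("convex hull is degenerate (< 3 points or all collinear)",
      class = "sensorlayout_degenerate_hull"
    )
  }
  polygon_area(hull)
}

# cross product (b-a) x (c-a); > 0 for a counter-clockwise turn
cross2 <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

# Graham scan returning hull vertices counter-clockwise (no repeated closure
# vertex). Collinear inputs collapse to fewer than 3 vertices.
graham_scan <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(pts)
  pivot_idx <- order(pts[, 2], pts[, 1])[1]
  pivot <- pts[pivot_idx, ]
  rest <- pts[-pivot_idx, , drop = FALSE]
  ang <- atan2(rest[, 2] - pivot[2], rest[, 1] - pivot[1])
  d2 <- (rest[, 1] - pivot[1])^2 + (rest[, 2] - pivot[2])^2
  rest <- rest[order(ang, d2), , drop = FALSE]
  stack <- matrix(0, nrow = n, ncol = 2)
  stack[1, ] <- pivot
  stack[2, ] <- rest[1, ]
  top <- 2L
  for (i in seq_len(nrow(rest))[-1]) {
    p <- rest[i, ]
    while (top >= 2L && cross2(stack[top - 1L, ], stack[top, ], p) <= 1e-12) {
      top <- top - 1L
      if (top < 2L) break
    }
    top <- top + 1L
    stack[top, ] <- p
  }
  stack[seq_len(top), , drop = FALSE]
}

# shoelace formula; vertices need not be closed
polygon_area <- function(poly) {
  u <- poly[, 1]; v <- poly[, 2]
  n <- length(u)
  j <- c(n, seq_len(n - 1L))
  abs(sum(u[j] * v - u * v[j])) / 2
}

#' Point-in-polygon test
#'
#' Ray-casting with explicit boundary handling: points on a polygon edge
#' (within `tol`) count as inside. This permissive convention keeps layouts
#' touching a sketched outline valid.
#'
#' @param p a point `c(u, v)` in mm, or an n x 2 matrix of points.
#' @param poly polygon vertices, an m x 2 matrix or data frame with columns
#'   `u`, `v` (simple, implicitly closed).
#' @param tol boundary tolerance in mm.
#' @return logical, one element per row of `p`.
#' @export
point_in_polygon <- function(p, poly, tol = 1e-9) {
  pts <- as_point_matrix(p)
  poly <- as_point_matrix(poly)
  if (nrow(poly) < 3) rlang::abort("polygon needs >= 3 vertices", class = "sensorlayout_geometry_error")
  vapply(seq_len(nrow(pts)), function(i) pip_one(pts[i, ], poly, tol), logical(1))
}

pip_one <- function(p, poly, tol) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  # boundary check first: distance to any edge within tol
  for (k in seq_len(n)) {
    if (seg_dist(p, poly[j[k], ], poly[k, ]) <= tol) return(TRUE)
  }
  # even-odd ray casting, ray towards +u
  inside <- FALSE
  for (k in seq_len(n)) {
    a <- poly[j[k], ]; b <- poly[k, ]
    if ((a[2] > p[2]) != (b[2] > p[2])) {
      x_int <- a[1] + (p[2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (p[1] < x_int) inside <- !inside
    }
  }
  inside
}

seg_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + t * ab - p)^2))
}

#' Distance from a point to a closed segment
#'
#' @param p point `c(u, v)`, mm.
#' @param a,b segment endpoints, mm; must differ.
#' @return Euclidean distance in mm.
#' @export
point_segment_distance <- function(p, a, b) {
  p <- as.numeric(p); a <- as.numeric(a); b <- as.numeric(b)
  if (all(a == b)) rlang::abort("degenerate segment: a == b", class = "sensorlayout_geometry_error")
  seg_dist(p, a, b)
}

#' Axial angle between an electrode pair and a muscle line
#'
#' The angle between the vector joining the two electrodes and the vector
#' joining the two muscle keypoints, theta = arccos(|k . e| / (|k||e|)).
#' A bipolar pair has no orientation sign, so the angle is folded into
#' \[0, 90\] degrees via the absolute dot product (an antiparallel pair is
#' perfectly aligned, angle 0).
#'
#' @param e1,e2 electrode centres `c(u, v)`, mm; must differ.
#' @param k1,k2 muscle-line keypoints `c(u, v)`, mm; must differ.
#' @return angle in degrees in \[0, 90\].
#' @export
pair_angle_to_line <- function(e1, e2, k1, k2) {
  e <- as.numeric(e2) - as.numeric(e1)
  k <- as.numeric(k2) - as.numeric(k1)
  ne <- sqrt(sum(e^2)); nk <- sqrt(sum(k^2))
  if (ne == 0 || nk == 0) {
    rlang::abort("zero-length vector in pair_angle_to_line", class = "sensorlayout_geometry_error")
  }
  ratio <- min(1, abs(sum(e * k)) / (ne * nk))
  acos(ratio) * 180 / pi
}
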