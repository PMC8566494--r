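# Geometry kernel: hull area, containment, distances, axial angles.

# gift-wrapping (Jarvis march) hull-area oracle, independent of the Graham
# scan implementation under test
gift_wrap_area <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- order(pts[, 1], pts[, 2])[1]
  hull_idx <- start
  current <- start
  repeat {
    nxt <- if (current == 1) 2 else 1
    for (j in seq_len(n)) {
      if (j == current) next
      cr <- (pts[nxt, 1] - pts[current, 1]) * (pts[j, 2] - pts[current, 2]) -
            (pts[nxt, 2] - pts[current, 2]) * (pts[j, 1] - pts[current, 1])
      d_nxt <- sum((pts[nxt, ] - pts[current, ])^2)
      d_j <- sum((pts[j, ] - pts[current, ])^2)
      if (cr < 0 || (cr == 0 && d_j > d_nxt)) nxt <- j
    }
    current <- nxt
    if (current == start) break
    hull_idx <- c(hull_idx, current)
  }
  hull <- pts[hull_idx, , drop = FALSE]
  u <- hull[, 1]; v <- hull[, 2]
  j <- c(length(u), seq_len(length(u) - 1))
  abs(sum(u[j] * v - u * v[j])) / 2
}

# winding-number point-in-polygon oracle
winding_inside <- function(p, poly) {
  n <- nrow(poly)
  wn <- 0
  for (k in seq_len(n)) {
    a <- poly[k, ]
    b <- poly[if (k == n) 1 else k + 1, ]
    # boundary counts as inside, matching the implementation's convention
    if (point_segment_distance(p, a, b) <= 1e-9) return(TRUE)
    if (a[2] <= p[2]) {
      if (b[2] > p[2] && (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) > 0) wn <- wn + 1
    } else {
      if (b[2] <= p[2] && (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) < 0) wn <- wn - 1
    }
  }
  wn != 0
}

test_that("convex hull area handles squares, interior points and degeneracy", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(convex_hull_area(sq), 1)
  expect_equal(convex_hull_area(rbind(sq, c(0.5, 0.5))), 1)
  expect_error(convex_hull_area(rbind(c(0, 0), c(1, 1))), class = "sensorlayout_degenerate_hull")
  expect_error(
    convex_hull_area(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))),
    class = "sensorlayout_degenerate_hull"
  )
})

test_that("convex hull area matches a gift-wrapping oracle on random point sets", {
  set.seed(42)
  for (rep in 1:5) {
    pts <- matrix(runif(400, 0, 10), ncol = 2)
    expect_equal(convex_hull_area(pts), gift_wrap_area(pts), tolerance = 1e-9)
  }
})

test_that("hull area is invariant under rigid motions", {
  set.seed(7)
  pts <- matrix(runif(60, 0, 10), ncol = 2)
  a0 <- convex_hull_area(pts)
  for (ang in c(0.3, 1.2, 2.9)) {
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    moved <- pts %*% rot + matrix(c(5, -3), nrow(pts), 2, byrow = TRUE)
    expect_equal(convex_hull_area(moved), a0, tolerance = 1e-7 * a0)
  }
})

test_that("point-in-polygon agrees with the winding-number oracle on a concave 12-gon", {
  poly <- rbind(
    c(0, 0), c(4, 0), c(4, 2), c(2, 2), c(2, 3), c(4, 3),
    c(4, 6), c(0, 6), c(0, 4), c(1, 4), c(1, 1), c(0, 1)
  )
  expect_true(point_in_polygon(c(0.5, 0.5), rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
  expect_false(point_in_polygon(c(2, 2), rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
  set.seed(99)
  pts <- cbind(runif(1000, -1, 5), runif(1000, -1, 7))
  got <- point_in_polygon(pts, poly)
  want <- vapply(seq_len(nrow(pts)), function(i) winding_inside(pts[i, ], poly), logical(1))
  expect_identical(got, want)
  # every vertex of a polygon is inside it
  expect_true(all(point_in_polygon(poly, poly)))
})

test_that("point-segment distance clamps to endpoints and rejects degenerate segments", {
  expect_equal(point_segment_distance(c(0.5, 0), c(0, 0), c(1, 0)), 0)
  expect_equal(point_segment_distance(c(0, 1), c(-1, 0), c(1, 0)), 1)
  expect_equal(point_segment_distance(c(3, 4), c(-1, 0), c(1, 0)), sqrt(4 + 16))
  expect_error(point_segment_distance(c(0, 0), c(1, 1), c(1, 1)), class = "sensorlayout_geometry_error")
})

test_that("pair angle is axial, symmetric and folded into [0, 90]", {
  k1 <- c(0, 0); k2 <- c(10, 0)
  expect_equal(pair_angle_to_line(c(0, 0), c(5, 0), k1, k2), 0)
  expect_equal(pair_angle_to_line(c(0, 0), c(0, 5), k1, k2), 90)
  # antiparallel folds to 0, not 180
  expect_equal(pair_angle_to_line(c(5, 0), c(0, 0), k1, k2), 0)
  set.seed(3)
  for (i in 1:20) {
    e1 <- runif(2, -5, 5); e2 <- runif(2, -5, 5)
    if (all(e1 == e2)) next
    a <- pair_angle_to_line(e1, e2, k1, k2)
    expect_equal(a, pair_angle_to_line(e2, e1, k1, k2))
    expect_gte(a, 0); expect_lte(a, 90)
  }
  expect_error(pair_angle_to_line(c(0, 0), c(0, 0), k1, k2), class = "sensorlayout_geometry_error")
})
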