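# Polygon primitives and boolean operations.

test_that("circle area converges to pi r^2 and is centered", {
  p <- circle(c(0, 0), 1, 3600)
  expect_lt(abs(poly_area(p) - pi), 1e-4)
  sq <- circle(c(2, 3), 1.5, 4)
  expect_equal(poly_area(sq), 2 * 1.5^2, tolerance = 1e-9)
  v <- ring_open(p$rings[[1]])
  expect_equal(colMeans(v), c(0, 0), tolerance = 1e-9)
  expect_error(circle(c(0, 0), 0), "positive")
  expect_error(circle(c(0, 0), -1), "positive")
})

test_that("ellipse matches the circle degenerately and pi*a*b in area", {
  e <- ellipse(c(0.3, 0.4), c(0.2, 0.2), 0, 3600)
  c0 <- circle(c(0.3, 0.4), 0.2, 3600)
  expect_equal(poly_area(e), poly_area(c0), tolerance = 1e-12)
  e2 <- ellipse(c(0, 0), c(2, 1), 30, 3600)
  expect_lt(abs(poly_area(e2) - 2 * pi), 1e-3)
  # rotating by 180 degrees maps the vertex set onto itself
  va <- ring_open(ellipse(c(0, 0), c(2, 1), 0, 360)$rings[[1]])
  vb <- ring_open(ellipse(c(0, 0), c(2, 1), 180, 360)$rings[[1]])
  key <- function(m) sort(paste(round(m[, 1], 9), round(m[, 2], 9)))
  expect_identical(key(va), key(vb))
  expect_error(ellipse(c(0, 0), c(0, 1)), "positive")
})

test_that("triangle builds CCW polygons and rejects collinear input", {
  t1 <- triangle(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(poly_area(t1), 0.5, tolerance = 1e-12)
  # clockwise input is re-oriented, not negated
  t2 <- triangle(rbind(c(0, 0), c(0, 1), c(1, 0)))
  expect_equal(poly_area(t2), 0.5, tolerance = 1e-12)
  expect_error(triangle(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
})

test_that("rounded rectangle area follows the closed form", {
  r0 <- rounded_rectangle(c(0, 0), 2, 1, 0)
  expect_equal(poly_area(r0), 2, tolerance = 1e-12)
  rr <- rounded_rectangle(c(0, 0), 2, 1, 0.25, n_vertices = 2880)
  expect_lt(abs(poly_area(rr) - (2 * 1 - (4 - pi) * 0.25^2)), 1e-4)
  expect_error(rounded_rectangle(c(0, 0), 0.4, 1, 0.25), "exceed")
  expect_error(rounded_rectangle(c(0, 0), 1, 1, -0.1), "non-negative")
})

test_that("two-circle intersection matches the closed-form lens area", {
  # r1 = r2 = r, center distance d: area = 2 r^2 acos(d/2r) - d/2 sqrt(4r^2 - d^2)
  for (case in list(c(1, 1), c(1, 0.5), c(0.7, 1.0), c(1.3, 0.4))) {
    r <- case[1]; d <- case[2]
    a <- circle(c(0, 0), r, 720)
    b <- circle(c(d, 0), r, 720)
    lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
    got <- poly_area(poly_intersect(a, b))
    expect_lt(abs(got - lens) / lens, 1e-3)
  }
})

test_that("boolean operations satisfy the set algebra", {
  set.seed(42)
  for (i in 1:8) {
    # random convex polygons (convex hulls of point clouds)
    mk <- function() {
      pts <- matrix(stats::runif(20, 0, 1), ncol = 2)
      pts <- pts[grDevices::chull(pts), , drop = FALSE]
      poly_shape(pts[nrow(pts):1, , drop = FALSE])  # chull is clockwise
    }
    a <- mk(); b <- mk()
    ai <- poly_area(poly_intersect(a, b))
    expect_equal(ai, poly_area(poly_intersect(b, a)), tolerance = 1e-9)
    au <- poly_area(poly_union(a, b))
    expect_equal(au, poly_area(poly_union(b, a)), tolerance = 1e-9)
    # inclusion-exclusion
    expect_equal(au, poly_area(a) + poly_area(b) - ai, tolerance = 1e-7)
    # a \ b is disjoint from b
    d <- poly_difference(a, b)
    expect_lt(poly_area(poly_intersect(d, b)), 1e-7)
    expect_equal(poly_area(d), poly_area(a) - ai, tolerance = 1e-7)
  }
})

test_that("idempotent and degenerate boolean cases", {
  a <- circle(c(0, 0), 1)
  expect_true(poly_is_empty(poly_difference(a, a)))
  expect_equal(poly_area(poly_union(a, a)), poly_area(a), tolerance = 1e-12)
  expect_equal(poly_area(poly_intersect(a, a)), poly_area(a), tolerance = 1e-12)
  b <- circle(c(5, 0), 1)
  expect_true(poly_is_empty(poly_intersect(a, b)))
  expect_equal(poly_area(poly_union(a, b)),
               poly_area(a) + poly_area(b), tolerance = 1e-12)
  # shared-edge rectangles: no sliver, no double count
  s1 <- poly_shape(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  s2 <- poly_shape(cbind(c(1, 2, 2, 1), c(0, 0, 1, 1)))
  expect_equal(poly_area(poly_union(s1, s2)), 2, tolerance = 1e-12)
  expect_true(poly_is_empty(poly_intersect(s1, s2)))
  expect_equal(poly_area(poly_difference(s1, s2)), 1, tolerance = 1e-12)
})

test_that("difference can punch holes and intersections respect them", {
  big <- poly_shape(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)))
  small <- poly_shape(cbind(c(1, 2, 2, 1), c(1, 1, 2, 2)))
  donut <- poly_difference(big, small)
  expect_equal(poly_area(donut), 15, tolerance = 1e-12)
  expect_length(donut$rings, 2)
  probe <- poly_shape(cbind(c(0.5, 2.5, 2.5, 0.5), c(0.5, 0.5, 2.5, 2.5)))
  expect_equal(poly_area(poly_intersect(donut, probe)), 4 - 1,
               tolerance = 1e-12)
  expect_false(point_in_poly(rbind(c(1.5, 1.5)), donut))
  expect_true(point_in_poly(rbind(c(3, 3)), donut))
})

test_that("self-intersecting input is rejected with the ring named", {
  bow <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(poly_shape(bow), "ring 1 is self-intersecting")
})

test_that("boolean results are deterministic", {
  a <- ellipse(c(0.4, 0.5), c(0.3, 0.15), 30)
  b <- ellipse(c(0.6, 0.5), c(0.3, 0.15), -30)
  r1 <- poly_intersect(a, b)
  r2 <- poly_intersect(a, b)
  expect_identical(r1$rings, r2$rings)
})
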