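test_that("bezier evaluation honours the quadratic form and its domain", {
  crv <- bezier3d(c(0, 0, 0), c(1, 2, 0), c(2, 0, 0))
  expect_equal(bezier_point(crv, 0), c(x = 0, y = 0, z = 0))
  expect_equal(bezier_point(crv, 1), c(x = 2, y = 0, z = 0))
  expect_equal(bezier_point(crv, 0.5), c(x = 1, y = 1, z = 0))
  expect_error(bezier_point(crv, 1.2), "outside")
  expect_silent(bezier_point(crv, 1.2, extend = TRUE))
  expect_error(bezier3d(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0)), "chord")
  expect_error(bezier3d(c(0, 0, NA), c(1, 1, 1), c(2, 0, 0)), "finite")
})

test_that("derivatives match the closed form and finite differences", {
  crv <- bezier3d(c(0, 0, 0), c(1, 2, 0), c(2, 0, 0))
  d <- bezier_derivatives(crv, 0)
  expect_equal(d$d1, c(x = 2, y = 4, z = 0))
  expect_equal(d$d2, c(x = 0, y = -8, z = 0))
  straight <- bezier3d(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(bezier_derivatives(straight, 0.3)$d2, c(x = 0, y = 0, z = 0))
  set.seed(11)
  h <- 1e-5
  for (i in 1:20) {
    crv <- random_curve()
    s <- runif(1, 0.1, 0.9)
    fd1 <- (bezier_point(crv, s + h) - bezier_point(crv, s - h)) / (2 * h)
    fd2 <- (bezier_point(crv, s + h) - 2 * bezier_point(crv, s) +
              bezier_point(crv, s - h)) / h^2
    d <- bezier_derivatives(crv, s)
    expect_lt(max(abs(fd1 - d$d1)), 1e-6)
    expect_lt(max(abs(fd2 - d$d2)), 1e-3)
  }
})

test_that("arc length matches straight lines, scaling and a polyline oracle", {
  straight <- bezier3d(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(bezier_arc_length(straight), 2, tolerance = 1e-10)
  crv <- bezier3d(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))
  doubled <- bezier3d(c(0, 0, 0), c(2, 2, 0), c(4, 0, 0))
  expect_equal(bezier_arc_length(doubled), 2 * bezier_arc_length(crv),
               tolerance = 1e-9)
  # dense polyline summation as the independent oracle
  s <- seq(0, 1, length.out = 1e5 + 1)
  p <- bezier_point(crv, s)
  oracle <- sum(sqrt(rowSums(diff(p)^2)))
  expect_equal(bezier_arc_length(crv), oracle, tolerance = 1e-6)
  expect_error(
    bezier_arc_length(structure(matrix(1, 3, 3), class = "bezier3d")),
    "degenerate")
  expect_error(bezier_arc_length(crv, 0.7, 0.2), "s_from")
})

test_that("arc length is additive over subintervals", {
  set.seed(21)
  for (i in 1:10) {
    crv <- random_curve()
    a <- runif(1, 0.2, 0.8)
    expect_equal(bezier_arc_length(crv, 0, a) + bezier_arc_length(crv, a, 1),
                 bezier_arc_length(crv, 0, 1), tolerance = 1e-8)
  }
})

# independent oracle: curvature from the circumradius of three nearby points
circumcurvature <- function(crv, s, h = 1e-3) {
  p <- bezier_point(crv, c(s - h, s, s + h), extend = TRUE)
  a <- sqrt(sum((p[1, ] - p[2, ])^2))
  b <- sqrt(sum((p[2, ] - p[3, ])^2))
  cc <- sqrt(sum((p[1, ] - p[3, ])^2))
  v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
  area <- sqrt(sum((c(v1[2] * v2[3] - v1[3] * v2[2],
                      v1[3] * v2[1] - v1[1] * v2[3],
                      v1[1] * v2[2] - v1[2] * v2[1]))^2)) / 2
  4 * area / (a * b * cc)
}

test_that("3D curvature matches the osculating-circle oracle and is rigid-motion invariant", {
  straight <- bezier3d(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(curvature3d(straight, 0.5), 0)
  crv <- bezier3d(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))
  expect_equal(curvature3d(crv, 0), 1 / (2 * sqrt(2)), tolerance = 1e-9)
  expect_equal(curvature3d(crv, 0), circumcurvature(crv, 0), tolerance = 1e-6)
  set.seed(31)
  for (i in 1:10) {
    crv <- random_curve()
    s <- runif(1)
    R <- rotation_from_angles(runif(1, -3, 3), runif(1, -1.4, 1.4),
                              runif(1, -3, 3))
    tr <- runif(3, -50, 50)
    mm <- t(R %*% t(unclass(crv))) + rep(1, 3) %o% tr
    moved <- bezier3d(mm[1, ], mm[2, ], mm[3, ])
    expect_lt(abs(curvature3d(moved, s) - curvature3d(crv, s)), 1e-9)
    expect_lt(abs(curvature3d(crv, s) - circumcurvature(crv, s)), 1e-6)
  }
  # curvature in mm^-1 is the pixel value divided by the pixel pitch
  expect_equal(curvature3d(crv, 0, pixel_mm = 0.047),
               curvature3d(crv, 0) / 0.047)
})

test_that("planar curvatures are signed, plane-consistent and roll-sensitive", {
  crv <- bezier3d(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))
  expect_equal(curvature_planar(crv, 0, "horizontal"), -1 / (2 * sqrt(2)),
               tolerance = 1e-9)
  # symbolic differentiation oracle at generic s
  s <- 0.3
  d <- bezier_derivatives(crv, s)
  expected <- (d$d1["x"] * d$d2["y"] - d$d2["x"] * d$d1["y"]) /
    (d$d1["x"]^2 + d$d1["y"]^2)^1.5
  expect_equal(curvature_planar(crv, s, "horizontal"), unname(expected))
  # a curve confined to the x-z plane has zero horizontal curvature
  xz <- bezier3d(c(0, 0, 0), c(1, 0, 1), c(2, 0, 0))
  expect_equal(curvature_planar(xz, 0, "horizontal"), 0)
  # planar horizontal curve: |kappa_h| equals kappa_3D
  expect_equal(abs(curvature_planar(crv, 0.4, "horizontal")),
               curvature3d(crv, 0.4), tolerance = 1e-9)
  # rolling a planar curve about its tangent changes kappa_h, not kappa_3D
  base <- bezier3d(c(0, 0, 0), c(30, 0, 0), c(60, 8, 0))
  k3 <- curvature3d(base, 0)
  kh <- curvature_planar(base, 0, "horizontal")
  R <- rotation_from_angles(0, 0, 1.0)     # roll about the x axis
  mm <- t(R %*% t(unclass(base)))
  rolled <- bezier3d(mm[1, ], mm[2, ], mm[3, ])
  expect_equal(curvature3d(rolled, 0), k3, tolerance = 1e-12)
  expect_gt(abs(curvature_planar(rolled, 0, "horizontal") - kh), 1e-3)
  expect_error(curvature_planar(bezier3d(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)),
                                0, "horizontal"), "projected tangent")
})

test_that("reparameterization traces the same parabola with unchanged curvature", {
  crv <- bezier3d(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0))
  same <- bezier_reparam(crv, 0, 1)
  expect_equal(unclass(same), unclass(crv), tolerance = 1e-12)
  half <- bezier_reparam(crv, 0, 0.5)
  expect_equal(bezier_point(half, 1), bezier_point(crv, 0.5),
               tolerance = 1e-12)
  ext <- bezier_reparam(crv, -0.2, 1.1)
  # dense point-set comparison at matched physical parameters
  s_parent <- seq(-0.2, 1.1, length.out = 101)
  s_child <- (s_parent + 0.2) / 1.3
  expect_equal(bezier_point(ext, s_child),
               bezier_point(crv, s_parent, extend = TRUE), tolerance = 1e-9)
  for (k in c(10, 50, 90)) {
    expect_equal(curvature3d(ext, s_child[k]),
                 curvature3d(crv, s_parent[k]), tolerance = 1e-9)
  }
  expect_error(bezier_reparam(crv, 0.5, 0.5), "s_new_start")
})
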