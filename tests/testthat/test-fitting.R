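test_that("the line integral is exact on constant images and flags out-of-frame curves", {
  img <- matrix(0.7, 100, 100)
  xy <- cbind(seq(10, 80, length.out = 64), seq(20, 60, length.out = 64))
  expect_equal(line_integral_cost(img, xy), 0.7, tolerance = 1e-12)
  far <- cbind(seq(-200, -100, length.out = 64), seq(20, 60, length.out = 64))
  expect_error(line_integral_cost(img, far), class = "whisker3d_out_of_frame")
})

test_that("the line integral separates on-ridge from background curves", {
  sc <- helper_scene(noise_sd = 0)
  sc$snout$enabled <- FALSE
  m <- helper_camera()
  crv <- whisker3d:::motion_state(helper_motion(), 1, sc)$curve
  fp <- render_frame_pair(list(crv), sc, m)
  s <- seq(0, 1, length.out = 64)
  on_xy <- project_horizontal(bezier_point(crv, s), m)
  expect_lt(line_integral_cost(fp$h, on_xy), 0.15)
  expect_gt(line_integral_cost(fp$h, on_xy + 10), 0.85)
})

test_that("regularizers follow their closed forms", {
  cp <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(temporal_regularizer(cp, cp, 1), 0)
  cp2 <- cp; cp2[2, ] <- cp2[2, ] + c(1, 0, 0)
  expect_equal(temporal_regularizer(cp2, cp, 1), 0.5)
  expect_equal(temporal_regularizer(cp2, cp, 2), 0.25)

  expect_equal(shape_regularizer(c(0, 0, 0), c(1, 5, 0), c(2, 0, 0), 1), 0)
  expect_equal(shape_regularizer(c(0, 0, 0), c(1.5, 0.3, 0), c(2, 0, 0), 1),
               0.125)
  set.seed(3)
  R <- rotation_from_angles(0.5, -0.8, 1.1)
  pts <- list(c(0, 0, 0), c(1.5, 0.3, 0), c(2, 0, 0))
  rot <- lapply(pts, function(p) drop(R %*% p) + c(5, -2, 7))
  expect_equal(shape_regularizer(rot[[1]], rot[[2]], rot[[3]], 1), 0.125,
               tolerance = 1e-12)
  expect_error(shape_regularizer(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0), 1),
               "chord")
})

test_that("control-point extrapolation is linear with a copy fallback", {
  c1 <- bezier3d(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  c2 <- bezier3d(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_equal(extrapolate_controls(list(c1)), unclass(c1))
  out <- extrapolate_controls(list(c1, c2))
  expect_equal(out[1, ], c(x = 2, y = 0, z = 0))
  const <- extrapolate_controls(list(c2, c2))
  expect_equal(const, unclass(c2))
  expect_error(extrapolate_controls(list()), "empty")
})

test_that("total cost decomposes and reduces to image evidence for huge gains", {
  sc <- helper_scene()
  m <- helper_camera()
  scn <- generate_whisking_sequence(sc, helper_motion(), 3, m, seed = 5)
  crv <- whisker3d:::track_row_curve(scn$truth[1, ])
  shifted <- unclass(crv) + 1
  cost <- total_cost(scn$frames[[1]], crv, shifted, regularizer_weights(),
                     m)
  expect_equal(cost$E, cost$Eh + cost$Ev + cost$R1 + cost$R2,
               tolerance = 1e-12)
  huge <- total_cost(scn$frames[[1]], crv, shifted,
                     regularizer_weights(1e12, 1e12), m)
  expect_equal(huge$E, huge$Eh + huge$Ev, tolerance = 1e-9)
  # on-whisker curve with consistent prediction beats a displaced one
  mm <- unclass(crv) + 10
  worse <- total_cost(scn$frames[[1]], bezier3d(mm[1, ], mm[2, ], mm[3, ]),
                      mm, regularizer_weights(), m)
  expect_lt(cost$E, worse$E)
})

test_that("the optimizer searches exactly 7 scalars orthogonal to the endpoint tangents", {
  seed <- bezier3d(c(0, 0, 0), c(30, 4, 2), c(60, 0, -3))
  par <- fit_parameterization(seed)
  expect_identical(par$n_par, 7L)
  set.seed(8)
  for (i in 1:20) {
    p <- rnorm(7)
    moved <- par$make_curve(p)
    d0 <- unclass(moved)[1, ] - unclass(seed)[1, ]
    d2 <- unclass(moved)[3, ] - unclass(seed)[3, ]
    expect_lt(abs(sum(d0 * par$tangent0)), 1e-9)
    expect_lt(abs(sum(d2 * par$tangent1)), 1e-9)
  }
  # the parameterization is faithful: p = 0 returns the seed
  expect_equal(unclass(par$make_curve(rep(0, 7))), unclass(seed))
})

test_that("frame fits recover the whisker and never cost more than the seed", {
  sc <- helper_scene(noise_sd = 0)
  m <- helper_camera()
  scn <- generate_whisking_sequence(sc, helper_motion(), 3, m, seed = 5)
  fp <- scn$frames[[1]]
  crv <- whisker3d:::track_row_curve(scn$truth[1, ])
  w <- regularizer_weights()
  fit <- fit_frame(fp, crv, unclass(crv), w, m)
  expect_lt(max(abs(unclass(fit$curve) - unclass(crv))), 0.25)
  # whisker displaced from the seed: normal-plane recovery
  sh <- unclass(crv); sh[, 3] <- sh[, 3] + 2   # 2 px dorsal shift
  seed2 <- bezier3d(sh[1, ], sh[2, ], sh[3, ])
  fit2 <- fit_frame(fp, seed2, sh, w, m)
  expect_lt(sqrt(mean((unclass(fit2$curve) - unclass(crv))^2)), 0.5)
  # cost never increases relative to the seed
  set.seed(13)
  for (i in 1:5) {
    jit <- unclass(crv) + matrix(rnorm(9, 0, 1.5), 3, 3)
    seedj <- bezier3d(jit[1, ], jit[2, ], jit[3, ])
    fitj <- fit_frame(fp, seedj, jit, w, m)
    seed_cost <- total_cost(fp, seedj, jit, w, m)
    expect_lte(fitj$cost$E, seed_cost$E + 1e-9)
  }
})

test_that("a seed in empty background stays above the lock threshold", {
  sc <- helper_scene()
  m <- helper_camera()
  scn <- generate_whisking_sequence(sc, helper_motion(), 3, m, seed = 5)
  fp <- scn$frames[[1]]
  crv <- whisker3d:::track_row_curve(scn$truth[1, ])
  thr <- estimate_lock_threshold(fp, crv, m)
  far <- unclass(crv); far[, 1] <- far[, 1] - 60; far[, 2] <- far[, 2] - 60
  seed <- bezier3d(far[1, ], far[2, ], far[3, ])
  fit <- fit_frame(fp, seed, far, regularizer_weights(), m)
  expect_gt(fit$cost$E, thr)
})

test_that("a tiny sigma1 pins the fit to the prediction, a huge one frees it", {
  sc <- helper_scene(noise_sd = 0)
  m <- helper_camera()
  scn <- generate_whisking_sequence(sc, helper_motion(), 3, m, seed = 5)
  fp <- scn$frames[[1]]
  crv <- whisker3d:::track_row_curve(scn$truth[1, ])
  off <- unclass(crv); off[, 3] <- off[, 3] + 2
  seed <- bezier3d(off[1, ], off[2, ], off[3, ])
  pinned <- fit_frame(fp, seed, off, regularizer_weights(1e-4, 50), m)
  freed <- fit_frame(fp, seed, off, regularizer_weights(1e6, 50), m)
  d_pin <- max(abs(unclass(pinned$curve) - off))
  d_free <- max(abs(unclass(freed$curve) - off))
  expect_lt(d_pin, 0.05)
  expect_gt(d_free, 1)
  expect_lt(max(abs(unclass(freed$curve) - unclass(crv))), 0.6)
})

test_that("snout extrapolation matches analytic and dense-sampling oracles", {
  m <- helper_camera()
  # straight curve towards a straight contour: exact line intersection
  crv <- bezier3d(c(100, 100, 120), c(100, 80, 120), c(100, 60, 120))
  ct <- snout_contour("horizontal", 0:239, rep(110, 240), side = "high")
  hit <- extrapolate_to_snout(crv, ct, m)
  expect_equal(unname(hit$point[2]), 110, tolerance = 1e-6)
  expect_equal(hit$distance, 10, tolerance = 1e-6)
  # base already on the contour
  crv2 <- bezier3d(c(100, 110, 120), c(100, 90, 120), c(100, 70, 120))
  hit2 <- extrapolate_to_snout(crv2, ct, m)
  expect_equal(hit2$distance, 0, tolerance = 1e-9)
  # curved curve against a curved contour vs dense-sampling root search
  crv3 <- bezier3d(c(120, 100, 120), c(110, 75, 122), c(95, 52, 125))
  xs <- 0:239
  ct3 <- snout_contour("horizontal", xs, 104 + 0.02 * (xs - 120)^2 / 10,
                       side = "high")
  hit3 <- extrapolate_to_snout(crv3, ct3, m)
  sgrid <- seq(0, -2, length.out = 20001)
  p <- bezier_point(crv3, sgrid, extend = TRUE)
  gap <- p[, 2] - whisker3d:::contour_at(ct3, p[, 1])
  cross <- which(gap >= 0)[1]
  expect_equal(unname(sqrt(sum((hit3$point - p[cross, ])^2))), 0,
               tolerance = 0.1)
  # no crossing within range
  ct4 <- snout_contour("horizontal", 0:239, rep(235, 240), side = "high")
  expect_error(extrapolate_to_snout(crv, ct4, m),
               class = "whisker3d_no_intersection")
})

test_that("renormalization restores both references exactly and preserves shape", {
  m <- helper_camera()
  ct <- snout_contour("horizontal", 0:239, rep(110, 240), side = "high")
  crv <- bezier3d(c(100, 100, 120), c(112, 80, 124), c(120, 55, 121))
  len <- bezier_arc_length(crv)
  hit <- extrapolate_to_snout(crv, ct, m)
  # already satisfying both references: unchanged
  same <- renormalize_curve(crv, len, hit$distance, ct, m)
  expect_lt(max(abs(unclass(same) - unclass(crv))), 1e-7)
  expect_true(attr(same, "renormalized"))
  # arc length 10% over reference: restored to 1e-6
  rn <- renormalize_curve(crv, len / 1.1, hit$distance, ct, m)
  expect_equal(bezier_arc_length(rn), len / 1.1, tolerance = 1e-6)
  hit_rn <- extrapolate_to_snout(rn, ct, m)
  expect_equal(hit_rn$distance, hit$distance, tolerance = 0.1)
  # curvature at matched points unchanged (same parabola)
  expect_equal(curvature3d(rn, 0), curvature3d(crv, 0), tolerance = 1e-6)
  # missed contour: skipped with flag
  far_ct <- snout_contour("horizontal", 0:239, rep(235, 240), side = "high")
  sk <- renormalize_curve(crv, len, 10, far_ct, m)
  expect_false(attr(sk, "renormalized"))
  expect_equal(unclass(sk), unclass(crv), ignore_attr = TRUE)
})
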