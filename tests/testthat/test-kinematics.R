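test_that("the whisker frame is the tangent / bending-direction / normal triple", {
  crv <- bezier3d(c(0, 0, 0), c(1, 0, 0), c(2, 2, 0))
  M <- whisker_frame(crv)
  expect_equal(unname(M[, 1]), c(1, 0, 0))
  expect_equal(unname(M[, 2]), c(0, 1, 0))
  expect_equal(unname(M[, 3]), c(0, 0, 1))
  set.seed(2)
  for (i in 1:20) {
    M <- whisker_frame(random_curve())
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
    expect_equal(det(M), 1, tolerance = 1e-9)
  }
  expect_error(whisker_frame(bezier3d(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "straight")
})

test_that("Euler decomposition inverts composition and matches direct minimization", {
  expect_equal(pose_angles(diag(3)),
               list(theta = 0, phi = 0, zeta = 0, gimbal_lock = FALSE))
  a30 <- pose_angles(compose_pose(30, 0, 0))
  expect_equal(a30$theta, 30, tolerance = 1e-9)
  expect_equal(abs(a30$phi) + abs(a30$zeta), 0, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:50) {
    tr <- runif(3, -80, 80)
    ang <- pose_angles(compose_pose(tr[1], tr[2], tr[3]))
    expect_equal(c(ang$theta, ang$phi, ang$zeta), tr, tolerance = 1e-9)
    expect_false(ang$gimbal_lock)
  }
  # independent oracle: coarse grid + local refinement of the alignment
  # residual that the decomposition minimises
  direct_min <- function(M) {
    obj <- function(p) whisker3d:::pose_residual(p[1], p[2], p[3], M,
                                                 degrees = FALSE)
    grid <- as.matrix(expand.grid(theta = seq(-pi, pi, length.out = 13),
                                  phi = seq(-1.3, 1.3, length.out = 9),
                                  zeta = seq(-pi, pi, length.out = 13)))
    best <- grid[which.min(apply(grid, 1, obj)), ]
    stats::optim(best, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-15))$par
  }
  for (tr in list(c(25, -35, 60), c(-70, 10, -120), c(5, 55, 170))) {
    M <- compose_pose(tr[1], tr[2], tr[3])
    ang <- pose_angles(M, degrees = FALSE)
    oracle <- direct_min(M)
    expect_equal(c(ang$theta, ang$phi, ang$zeta), unname(oracle),
                 tolerance = 1e-6)
    expect_lt(whisker3d:::pose_residual(ang$theta, ang$phi, ang$zeta, M,
                                        degrees = FALSE), 1e-12)
  }
})

test_that("azimuth agrees with the planar tangent-projection definition", {
  set.seed(6)
  for (i in 1:20) {
    tr <- runif(3, -75, 75)
    M <- compose_pose(tr[1], tr[2], tr[3])
    planar <- atan2(M[2, 1], M[1, 1]) * 180 / pi
    expect_equal(pose_angles(M)$theta, planar, tolerance = 1e-9)
  }
})

test_that("near gimbal lock is flagged and still recomposes", {
  M <- compose_pose(40, 89.95, 10)
  ang <- pose_angles(M)
  expect_true(ang$gimbal_lock)
  M2 <- compose_pose(ang$theta, ang$phi, ang$zeta)
  expect_lt(max(abs(M2[, 1] - M[, 1])), 1e-2)
})

test_that("the decomposition residual is locally optimal", {
  M <- compose_pose(25, -35, 60)
  ang <- pose_angles(M, degrees = FALSE)
  r0 <- whisker3d:::pose_residual(ang$theta, ang$phi, ang$zeta, M,
                                  degrees = FALSE)
  set.seed(7)
  for (i in 1:20) {
    p <- c(ang$theta, ang$phi, ang$zeta) + rnorm(3, 0, 0.01)
    expect_gte(whisker3d:::pose_residual(p[1], p[2], p[3], M,
                                         degrees = FALSE), r0)
  }
})

test_that("pose and curvature series handle static, lost and unwrapped frames", {
  fx <- small_tracked_fixture()
  # static synthetic track built directly (no images needed)
  mk_row <- function(f, crv, status = "tracked") {
    tibble::tibble(frame = f, whisker_id = "w1",
                   !!!whisker3d:::curve_to_cols(crv),
                   E = 0.1, Eh = 0.05, Ev = 0.05, R1 = 0, R2 = 0,
                   status = status)
  }
  crv <- bezier3d(c(0, 0, 0), c(30, 2, 1), c(60, 10, 4))
  tr <- whisker3d:::new_whisker_tracks(dplyr::bind_rows(
    lapply(1:6, function(f) mk_row(f, crv))))
  pose <- pose_series(tr)
  expect_lt(diff(range(pose$theta)), 0.1)
  expect_lt(diff(range(pose$zeta)), 0.1)
  # lost frames carry NA, no interpolation
  tr$status[3] <- "lost"
  pose2 <- pose_series(tr)
  expect_true(is.na(pose2$theta[3]))
  expect_false(anyNA(pose2$theta[-3]))
  # roll unwrapping across the +/-180 seam
  zetas <- c(150, 170, -170, -150)     # a continuous roll through 180
  rows <- lapply(seq_along(zetas), function(f) {
    base <- whisker3d:::canonical_segment(0.01, 60)
    M <- compose_pose(0, 0, zetas[f])
    w <- t(M %*% t(base))
    mk_row(f, bezier3d(w[1, ], w[2, ], w[3, ]))
  })
  pose3 <- pose_series(whisker3d:::new_whisker_tracks(dplyr::bind_rows(rows)))
  expect_equal(pose3$zeta, c(150, 170, 190, 210), tolerance = 1e-6)
})

test_that("curvature series convert units and propagate missing frames", {
  fx <- small_tracked_fixture()
  cs_px <- curvature_series(fx$tracks, pixel_mm = 1)
  cs_mm <- curvature_series(fx$tracks, pixel_mm = 0.047)
  ok <- !is.na(cs_px$kappa3d)
  expect_equal(cs_mm$kappa3d[ok], cs_px$kappa3d[ok] / 0.047)
  # straight whisker: zero 3D curvature every frame
  straight <- whisker3d:::new_whisker_tracks(tibble::tibble(
    frame = 1:3, whisker_id = "w1",
    cp0x = 0, cp0y = 0, cp0z = 0, cp1x = 10, cp1y = 0, cp1z = 0,
    cp2x = 20, cp2y = 0, cp2z = 0,
    E = 0.1, Eh = 0.05, Ev = 0.05, R1 = 0, R2 = 0, status = "tracked"))
  cs <- curvature_series(straight, 0.047)
  expect_equal(cs$kappa3d, rep(0, 3))
})

test_that("rolling a rigid whisker swings planar curvatures but not kappa3d", {
  base <- whisker3d:::canonical_segment(0.15 * 0.047, 90)
  rows <- lapply(1:24, function(f) {
    M <- compose_pose(-100, 10, -180 + 15 * f)
    w <- t(M %*% t(base)) + rep(1, 3) %o% c(240, 320, 240)
    tibble::tibble(frame = f, whisker_id = "w1",
                   !!!whisker3d:::curve_to_cols(bezier3d(w[1, ], w[2, ], w[3, ])),
                   E = 0, Eh = 0, Ev = 0, R1 = 0, R2 = 0, status = "tracked")
  })
  cs <- curvature_series(whisker3d:::new_whisker_tracks(dplyr::bind_rows(rows)),
                         0.047)
  expect_lt(sd(cs$kappa3d) / mean(cs$kappa3d), 0.01)
  expect_gt(diff(range(cs$kappah)), 0.1)
  expect_gt(diff(range(cs$kappav)), 0.1)
})

test_that("delta-kappa is a shift-invariant baseline subtraction", {
  series <- tibble::tibble(frame = 1:10, whisker_id = "w1",
                           kappa3d = c(rep(0.15, 5), rep(0.2, 5)),
                           kappah = 0.1, kappav = 0.05,
                           status = "tracked")
  dk <- delta_kappa(series, resting_frames = 1:5)
  expect_equal(dk$kappa3d_0[1], 0.15)
  expect_equal(dk$dkappa3d, c(rep(0, 5), rep(0.05, 5)))
  shifted <- dplyr::mutate(series, kappa3d = kappa3d + 0.3)
  dk2 <- delta_kappa(shifted, 1:5)
  expect_equal(dk2$dkappa3d, dk$dkappa3d)
  expect_error(delta_kappa(series, integer(0)), "empty")
})

test_that("the kinematics table joins pose and shape with summaries and plots", {
  fx <- small_tracked_fixture()
  kin <- whisker_kinematics(fx$tracks, resting_frames = 1:5)
  expect_s3_class(kin, "whisker_kinematics")
  expect_true(all(c("theta", "phi", "zeta", "kappa3d", "dkappa3d") %in%
                    names(kin)))
  gl <- generics::glance(kin)
  expect_equal(gl$n_frames, 30)
  p <- ggplot2::autoplot(kin)
  expect_s3_class(p, "ggplot")
  p2 <- ggplot2::autoplot(fx$tracks, model = fx$scene$model)
  expect_s3_class(p2, "ggplot")
})
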