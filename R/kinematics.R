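#' Whisker-centric coordinate frame of a curve
#'
#' Unit vectors of the whisker-centred frame at the base of the curve:
#' `i'` along the tangent at `s = 0`, `j'` in the direction the curve bends
#' (from the second derivative, re-orthogonalised against `i'` because for a
#' general quadratic `b''` need not be perpendicular to the base tangent),
#' and `k' = i' x j'`. The frame is undefined for a straight curve, whose
#' bending plane (and hence roll angle) is arbitrary.
#'
#' @param curve A [bezier3d] curve.
#' @return 3x3 matrix with columns `i`, `j`, `k` (orthonormal).
#' @export
whisker_frame <- function(curve) {
  d <- bezier_derivatives(curve, 0)
  n1 <- sqrt(sum(d$d1^2))
  n2 <- sqrt(sum(d$d2^2))
  if (n1 < 1e-12) stop("zero tangent at s = 0")
  if (n2 < 1e-9 * n1)
    stop("straight curve: bending plane and roll are undefined")
  i <- d$d1 / n1
  j <- d$d2 - sum(d$d2 * i) * i
  nj <- sqrt(sum(j^2))
  if (nj < 1e-9 * n2)
    stop("degenerate curve: second derivative parallel to tangent; roll undefined")
  j <- j / nj
  k <- cross3(i, j)
  m <- cbind(i = i, j = j, k = k)
  rownames(m) <- c("x", "y", "z")
  m
}

#' Rotation matrix from azimuth, elevation and roll
#'
#' Intrinsic rotation sequence azimuth (about the dorso-ventral `z` axis),
#' then elevation (about the medio-lateral `y` axis, positive lifting the
#' whisker tip dorsally), then roll (about the whisker's own axis):
#' `R = Rz(theta) Ry(-phi) Rx(zeta)`. The columns of the result are the
#' whisker-frame unit vectors `i'`, `j'`, `k'` expressed in head coordinates.
#' Rotations use the standard algebraic matrices on coordinates; sign
#' conventions therefore follow the coordinate definitions (x posterior,
#' y medial, z dorsal).
#'
#' @param theta,phi,zeta Angles. Degrees unless `degrees = FALSE`.
#' @param degrees Interpret angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
compose_pose <- function(theta, phi, zeta, degrees = TRUE) {
  if (degrees) {
    theta <- theta * pi / 180; phi <- phi * pi / 180; zeta <- zeta * pi / 180
  }
  rot_z(theta) %*% rot_y(-phi) %*% rot_x(zeta)
}

#' Azimuth, elevation and roll of a whisker-centric frame
#'
#' Closed-form Euler decomposition of the rotation taking the head frame to
#' the whisker frame, in the intrinsic azimuth-elevation-roll order of
#' [compose_pose()]. Azimuth agrees with the classical planar definition
#' (angle between the `x` axis and the horizontal projection of the base
#' tangent) away from gimbal lock. Within 0.1 degrees of `|phi| = 90` the
#' azimuth and roll are only jointly determined; the returned angles still
#' recompose the frame but carry `gimbal_lock = TRUE`.
#'
#' @param frame 3x3 matrix with columns `i'`, `j'`, `k'` (e.g. from
#'   [whisker_frame()]), orthonormal to 1e-6.
#' @param degrees Return angles in degrees.
#' @return List with `theta`, `phi`, `zeta`, and `gimbal_lock` flag.
#' @export
pose_angles <- function(frame, degrees = TRUE) {
  M <- unname(as.matrix(frame))
  if (max(abs(crossprod(M) - diag(3))) > 1e-6)
    stop("frame is not orthonormal")
  sphi <- max(-1, min(1, M[3, 1]))
  phi <- asin(sphi)
  gimbal <- abs(abs(phi) - pi / 2) < 0.1 * pi / 180
  if (!gimbal) {
    theta <- atan2(M[2, 1], M[1, 1])
    zeta <- atan2(M[3, 2], M[3, 3])
  } else {
    # theta + / - zeta degenerate: report theta from the j' column, zeta = 0
    theta <- atan2(-M[1, 2], M[2, 2])
    zeta <- 0
  }
  s <- if (degrees) 180 / pi else 1
  list(theta = theta * s, phi = phi * s, zeta = zeta * s,
       gimbal_lock = gimbal)
}

# Sum-of-squares alignment residual of an angle triple against a frame
# (the quantity the closed-form decomposition minimises).
pose_residual <- function(theta, phi, zeta, frame, degrees = TRUE) {
  R <- t(compose_pose(theta, phi, zeta, degrees))
  sum((R %*% unname(as.matrix(frame)) - diag(3))^2)
}

#' Per-frame 3D pose of a tracked whisker
#'
#' Applies [whisker_frame()] and [pose_angles()] to every tracked frame of a
#' track table. Frames with a lost status, or where the frame is undefined
#' (straight curve), carry `NA`. Roll is unwrapped over time within each
#' whisker (jumps larger than 180 degrees between consecutive defined values
#' are removed).
#'
#' @param tracks A `whisker_tracks` tibble (see [track_video()]).
#' @param degrees Return angles in degrees.
#' @return Tibble with columns `frame`, `whisker_id`, `theta`, `phi`,
#'   `zeta`, `gimbal_lock`, `status`.
#' @export
pose_series <- function(tracks, degrees = TRUE) {
  stopifnot(is.data.frame(tracks))
  rows <- purrr::pmap(
    list(seq_len(nrow(tracks))),
    function(i) {
      row <- tracks[i, ]
      if (!(row$status %in% c("tracked", "curated")))
        return(list(theta = NA_real_, phi = NA_real_, zeta = NA_real_,
                    gimbal_lock = NA))
      ang <- tryCatch(
        pose_angles(whisker_frame(track_row_curve(row)), degrees = degrees),
        error = function(e) NULL)
      if (is.null(ang))
        list(theta = NA_real_, phi = NA_real_, zeta = NA_real_,
             gimbal_lock = NA)
      else ang[c("theta", "phi", "zeta", "gimbal_lock")]
    })
  out <- dplyr::bind_cols(
    tracks[, c("frame", "whisker_id")],
    dplyr::bind_rows(lapply(rows, tibble::as_tibble)),
    status = tracks$status)
  period <- if (degrees) 360 else 2 * pi
  out |>
    dplyr::group_by(.data$whisker_id) |>
    dplyr::mutate(zeta = unwrap_angle(.data$zeta, period)) |>
    dplyr::ungroup()
}

unwrap_angle <- function(z, period = 360) {
  ok <- which(!is.na(z))
  if (length(ok) < 2) return(z)
  v <- z[ok]
  jumps <- diff(v)
  corr <- cumsum(c(0, -round(jumps / period) * period))
  z[ok] <- v + corr
  z
}

#' Curvature time series of a tracked whisker
#'
#' 3D and planar curvatures at the base (`s = 0`) of every tracked curve,
#' converted to 1/mm with the camera pixel pitch. Planar curvatures use the
#' head-frame horizontal `(x, y)` and coronal `(z, y)` projections.
#'
#' @param tracks A `whisker_tracks` tibble.
#' @param pixel_mm Pixel pitch in mm/px.
#' @return Tibble with columns `frame`, `whisker_id`, `kappa3d`, `kappah`,
#'   `kappav` (1/mm), `status`.
#' @export
curvature_series <- function(tracks, pixel_mm = 0.047) {
  vals <- purrr::map(seq_len(nrow(tracks)), function(i) {
    row <- tracks[i, ]
    if (!(row$status %in% c("tracked", "curated")))
      return(list(kappa3d = NA_real_, kappah = NA_real_, kappav = NA_real_))
    crv <- track_row_curve(row)
    list(
      kappa3d = tryCatch(curvature3d(crv, 0, pixel_mm),
                         error = function(e) NA_real_),
      kappah = tryCatch(curvature_planar(crv, 0, "horizontal", pixel_mm),
                        error = function(e) NA_real_),
      kappav = tryCatch(curvature_planar(crv, 0, "vertical", pixel_mm),
                        error = function(e) NA_real_))
  })
  dplyr::bind_cols(tracks[, c("frame", "whisker_id")],
                   dplyr::bind_rows(lapply(vals, tibble::as_tibble)),
                   status = tracks$status)
}

#' Bending-moment proxy: curvature change from rest
#'
#' The change of 3D curvature from its contact-free resting value,
#' `dkappa3d = kappa3d - kappa3d_0`, is proportional to the bending moment
#' at the whisker base under quasi-static contact (the only nonzero moment
#' component for a zero-torsion curve). The resting curvature is the mean
#' over a user-specified set of free-whisking frames. Planar analogues
#' `dkappah` and `dkappav` are added for comparison.
#'
#' @param series Output of [curvature_series()].
#' @param resting_frames Frame indices over which the whisker is free from
#'   contact and at rest.
#' @return `series` with columns `kappa3d_0`, `dkappa3d`, `dkappah`,
#'   `dkappav` added.
#' @export
delta_kappa <- function(series, resting_frames) {
  if (length(resting_frames) == 0) stop("resting frame set is empty")
  rest <- dplyr::filter(series, .data$frame %in% resting_frames,
                        !is.na(.data$kappa3d))
  if (nrow(rest) == 0) stop("no tracked frames in the resting set")
  base <- rest |>
    dplyr::group_by(.data$whisker_id) |>
    dplyr::summarise(kappa3d_0 = mean(.data$kappa3d),
                     kappah_0 = mean(.data$kappah),
                     kappav_0 = mean(.data$kappav), .groups = "drop")
  series |>
    dplyr::left_join(base, by = "whisker_id") |>
    dplyr::mutate(dkappa3d = .data$kappa3d - .data$kappa3d_0,
                  dkappah = .data$kappah - .data$kappah_0,
                  dkappav = .data$kappav - .data$kappav_0) |>
    dplyr::select(-"kappah_0", -"kappav_0")
}

#' Full 3D kinematics table for a set of tracks
#'
#' Convenience wrapper joining [pose_series()] and [curvature_series()]
#' (plus [delta_kappa()] when resting frames are given) into one tidy table.
#'
#' @param tracks A `whisker_tracks` tibble.
#' @param pixel_mm Pixel pitch in mm/px.
#' @param resting_frames Optional frame indices for the resting-curvature
#'   reference.
#' @return A tibble of class `whisker_kinematics` with one row per frame per
#'   whisker.
#' @export
whisker_kinematics <- function(tracks, pixel_mm = 0.047,
                               resting_frames = NULL) {
  pose <- pose_series(tracks)
  curv <- curvature_series(tracks, pixel_mm)
  out <- dplyr::left_join(
    pose, dplyr::select(curv, -"status"),
    by = c("frame", "whisker_id"))
  if (!is.null(resting_frames)) out <- delta_kappa(out, resting_frames)
  class(out) <- c("whisker_kinematics", class(out))
  out
}

#' @method glance whisker_kinematics
#' @export
glance.whisker_kinematics <- function(x, ...) {
  x |>
    dplyr::group_by(.data$whisker_id) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      n_tracked = sum(!is.na(.data$theta)),
      theta_range = diff(range(.data$theta, na.rm = TRUE)),
      phi_range = diff(range(.data$phi, na.rm = TRUE)),
      zeta_range = diff(range(.data$zeta, na.rm = TRUE)),
      kappa3d_mean = mean(.data$kappa3d, na.rm = TRUE),
      kappa3d_sd = stats::sd(.data$kappa3d, na.rm = TRUE),
      .groups = "drop")
}

#' Plot 3D kinematic time series
#'
#' Angles (and curvatures, if present) per whisker over frames.
#'
#' @param object A `whisker_kinematics` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot whisker_kinematics
#' @export
autoplot.whisker_kinematics <- function(object, ...) {
  vars <- intersect(c("theta", "phi", "zeta", "kappa3d", "dkappa3d"),
                    names(object))
  long <- object |>
    dplyr::select("frame", "whisker_id", dplyr::all_of(vars)) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$frame, .data$value,
                                     colour = factor(.data$whisker_id))) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "frame", y = NULL, colour = "whisker") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
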