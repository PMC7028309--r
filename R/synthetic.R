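#' Synthetic stereo scene configuration
#'
#' Describes the rendered scene: image geometry, backlit contrast, the
#' Gaussian cross-section of whisker ridges, pixel noise, and the static
#' dark regions (snout, optional pole). Whiskers image dark on a light
#' background, as under infrared backlighting through a diffuser.
#'
#' @param image_size Integer `(rows, cols)`; both views share it.
#' @param pixel_mm Pixel pitch, mm/px.
#' @param background Background intensity (fraction of full scale).
#' @param whisker_contrast Depth of the whisker ridge below background; the
#'   ridge centre has intensity `background - whisker_contrast`.
#' @param ridge_sd Gaussian SD of the ridge cross-section, px (mouse
#'   whiskers image 2-3 px wide at the base).
#' @param noise_sd Additive i.i.d. Gaussian pixel noise SD (fraction of full
#'   scale); images are clipped to `[0, 1]` after adding it.
#' @param frame_rate Frames per second.
#' @param snout List describing the dark snout (or mount) region:
#'   `enabled`; horizontal-view contour `y0 + bow * ((x - cx)/cx)^2` with
#'   dark side `side_h` (`"high"` = dark at large `y`); vertical-view
#'   contour `v0 + v_bow * ((w - cw)/cw)^2` with dark side `side_v`;
#'   `intensity` of the dark region.
#' @param pole Optional occluder: list with `centre` `(x, y)` px, `radius`
#'   px and `intensity`; rendered as a disk in the horizontal view and a
#'   vertical band in the vertical view (the pole is vertical).
#' @param render_s Parameter range of each whisker that is rendered; the
#'   tracked segment is `[0, 1]`, the extension makes the image continue
#'   proximally into the snout and distally beyond the segment so that
#'   fitting is not artificially anchored by segment endpoints.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(480L, 480L), pixel_mm = 0.047,
                         background = 0.9, whisker_contrast = 0.85,
                         ridge_sd = 1.0, noise_sd = 0.02, frame_rate = 1000,
                         snout = list(enabled = TRUE, y0 = 330, bow = 30,
                                      side_h = "high", v0 = 370, v_bow = 10,
                                      side_v = "high", intensity = 0.12),
                         pole = NULL,
                         render_s = c(-0.3, 1.4)) {
  stopifnot(whisker_contrast > 0, noise_sd >= 0, ridge_sd > 0)
  structure(list(image_size = as.integer(image_size), pixel_mm = pixel_mm,
                 background = background, whisker_contrast = whisker_contrast,
                 ridge_sd = ridge_sd, noise_sd = noise_sd,
                 frame_rate = frame_rate, snout = snout, pole = pole,
                 render_s = render_s),
            class = "scene_config")
}

#' Phenomenological whisking motion model for one synthetic whisker
#'
#' Each whisker is a rigid planar parabola of intrinsic curvature `kappa0`
#' in its whisker-centric plane, rotated per frame by the pose
#' `R(theta(t), phi(t), zeta(t))` about a fixed base point. Azimuth is
#' sinusoidal, `theta(t) = theta0 + amp * sin(2 pi freq t + phase)`;
#' elevation and roll are linearly coupled to azimuth
#' (`phi = phi0 + c_phi (theta - theta0)`, `zeta = zeta0 + c_zeta (theta -
#' theta0)`), emulating the strong azimuth-elevation anti-correlation and
#' whisker-dependent roll coupling of natural whisking. Optional slip
#' events add an instantaneous azimuth offset from a given frame onward,
#' and an optional per-frame curvature offset emulates contact-induced
#' bending (non-rigid shape change).
#'
#' @param base Length-3 base point (px, head frame).
#' @param length_mm Arc-wise segment length, mm (converted to px via the
#'   scene pixel pitch; the chord of the rendered parabola).
#' @param kappa0_mm Intrinsic 3D curvature at the base, 1/mm.
#' @param theta0,amp,freq,phase Azimuth offset (deg), amplitude (deg),
#'   frequency (Hz) and phase (rad).
#' @param phi0,c_phi Elevation offset (deg) and azimuth-coupling slope.
#' @param zeta0,c_zeta Roll offset (deg) and azimuth-coupling slope.
#' @param slips Optional data frame with columns `frame`, `dtheta` (deg):
#'   persistent azimuth jumps applied from `frame` onward.
#' @param dkappa_mm Optional per-frame vector of curvature offsets (1/mm)
#'   added to `kappa0_mm` (recycled or truncated to the sequence length).
#' @param whisker_id Identifier carried into ground truth and tracks.
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(base = c(240, 327, 240), length_mm = 4.2,
                         kappa0_mm = 0.15, theta0 = -100, amp = 20,
                         freq = 10, phase = 0, phi0 = 5, c_phi = -0.4,
                         zeta0 = -30, c_zeta = 0.5, slips = NULL,
                         dkappa_mm = NULL, whisker_id = "w1") {
  stopifnot(amp >= 0, freq > 0)
  structure(list(base = as.numeric(base), length_mm = length_mm,
                 kappa0_mm = kappa0_mm, theta0 = theta0, amp = amp,
                 freq = freq, phase = phase, phi0 = phi0, c_phi = c_phi,
                 zeta0 = zeta0, c_zeta = c_zeta, slips = slips,
                 dkappa_mm = dkappa_mm, whisker_id = whisker_id),
            class = "motion_model")
}

#' A standard arrangement of synthetic whiskers
#'
#' `n` whiskers in up to two rows (dorsal/ventral) spread along the
#' anterior-posterior axis, with per-whisker phase offsets and slightly
#' different coupling slopes, emulating a multi-whisker field with moderate
#' overlap between neighbouring whiskers.
#'
#' @param n Number of whiskers (1..8).
#' @param scene A [scene_config] (for the snout geometry and pixel pitch).
#' @return List of [motion_model] objects.
#' @export
default_motion_set <- function(n = 8, scene = scene_config()) {
  stopifnot(n >= 1, n <= 8)
  xs <- rep(c(150, 215, 280, 345), 2)[seq_len(n)]
  zrow <- rep(c(262, 218), each = 4)[seq_len(n)]
  cx <- (scene$image_size[2] - 1) / 2
  purrr::map(seq_len(n), function(i) {
    ys <- scene$snout$y0 + scene$snout$bow * ((xs[i] - cx) / cx)^2
    motion_model(
      base = c(xs[i], ys - 3, zrow[i]),
      theta0 = -100 + 4 * ((i - 1) %% 4 - 1.5),
      amp = 20, freq = 10, phase = 0.25 * (i - 1),
      phi0 = 5, c_phi = -0.4 - 0.03 * (i - 1),
      zeta0 = -30 + 5 * (i - 1), c_zeta = 0.5 - 0.04 * (i - 1),
      whisker_id = paste0("w", i))
  })
}

# Canonical local control points of a planar parabolic segment with 3D
# curvature `kpx` (1/px) at s = 0, chord x-extent `L`, base at the origin,
# base tangent along +e1 and bending towards +e2. The segment is symmetric
# about the parabola vertex, so the middle control point's along-chord
# component lies exactly at the chord midpoint: control points of a
# quadratic arc are not unique, and this is the representative the shape
# regularizer selects, which makes ground-truth control points directly
# comparable with fitted ones. Because a parabola's curvature varies along
# it, the parameter curvature is solved (fixed point) so that the value at
# the base point equals `kpx`.
canonical_segment <- function(kpx, L) {
  a <- L / 2
  # the endpoint curvature of a symmetric quadratic segment of half-chord a
  # is at most ~0.385/a (attained at vertex curvature 1/(sqrt(2) a)); past
  # that, the requested bent shape leaves the representable family
  if (kpx * a >= 0.38)
    stop("segment too long for its base curvature: no symmetric quadratic ",
         "parameterization exists (kappa * half-chord = ",
         format(kpx * a, digits = 3), " >= 0.38); shorten the segment or ",
         "reduce the curvature")
  kp <- kpx
  if (kpx > 0) {
    g <- function(k) kpx * (1 + k^2 * a^2)^1.5 - k
    kp <- stats::uniroot(g, c(kpx, 1 / (sqrt(2) * a)), tol = 1e-14)$root
  }
  h <- kp * a^2 / 2
  S <- rbind(c(-a, h, 0), c(0, -h, 0), c(a, h, 0))
  S <- sweep(S, 2, S[1, ])              # base at origin
  gam <- atan(kp * a)                   # align base tangent with +e1
  t(rot_z(gam) %*% t(S))
}

# Pose and curve of one whisker at one frame.
motion_state <- function(motion, frame, scene) {
  t <- (frame - 1) / scene$frame_rate
  theta <- motion$theta0 + motion$amp * sin(2 * pi * motion$freq * t +
                                              motion$phase)
  if (!is.null(motion$slips)) {
    past <- motion$slips$frame <= frame
    theta <- theta + sum(motion$slips$dtheta[past])
  }
  dth <- theta - motion$theta0
  phi <- motion$phi0 + motion$c_phi * dth
  zeta <- motion$zeta0 + motion$c_zeta * dth
  kmm <- motion$kappa0_mm
  if (!is.null(motion$dkappa_mm)) {
    dk <- motion$dkappa_mm
    kmm <- kmm + if (frame <= length(dk)) dk[frame] else 0
  }
  L <- motion$length_mm / scene$pixel_mm
  kpx <- kmm * scene$pixel_mm
  local <- canonical_segment(kpx, L)
  M <- compose_pose(theta, phi, zeta)
  world <- t(M %*% t(local)) + rep(1, 3) %o% motion$base
  list(curve = bezier3d(world[1, ], world[2, ], world[3, ]),
       theta = theta, phi = phi, zeta = zeta, kappa3d_mm = kmm)
}

# Static dark-region overlays (snout, pole): a per-pixel mixing weight in
# [0, 1] for each view, with a ~1.5 px soft edge.
scene_overlays <- function(scene, model) {
  nr <- scene$image_size[1]; nc <- scene$image_size[2]
  mh <- NULL; mv <- NULL
  sn <- scene$snout
  if (isTRUE(sn$enabled)) {
    cx <- (nc - 1) / 2
    xs <- 0:(nc - 1)
    ys_contour <- sn$y0 + sn$bow * ((xs - cx) / cx)^2
    yy <- matrix(0:(nr - 1), nr, nc)
    cc <- matrix(ys_contour, nr, nc, byrow = TRUE)
    sgn <- if (identical(sn$side_h, "high")) 1 else -1
    mh <- stats::plogis(sgn * (yy - cc) / 0.75)
    cw <- (nr - 1) / 2
    ws <- 0:(nr - 1)
    vs_contour <- sn$v0 + sn$v_bow * ((ws - cw) / cw)^2
    vv <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    ccv <- matrix(vs_contour, nr, nc)
    sgnv <- if (identical(sn$side_v, "high")) 1 else -1
    mv <- stats::plogis(sgnv * (vv - ccv) / 0.75)
  }
  ph <- NULL; pv <- NULL
  if (!is.null(scene$pole)) {
    po <- scene$pole
    xx <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    yy <- matrix(0:(nr - 1), nr, nc)
    d <- sqrt((xx - po$centre[1])^2 + (yy - po$centre[2])^2)
    ph <- stats::plogis(-(d - po$radius) / 0.75)
    # the vertical pole images as the (slightly tilted) epipolar line of
    # its horizontal-view position: v(w) along the z-column of V
    z0 <- (nr - 1) / 2
    p0 <- project_vertical(c(po$centre[1], po$centre[2], z0), model)
    slope <- model$V[1, 3] / model$V[2, 3]
    vv <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    ww <- matrix(0:(nr - 1), nr, nc)
    pv <- stats::plogis(-(abs(vv - (p0[1] + slope * (ww - p0[2]))) -
                            po$radius) / 0.75)
  }
  list(snout_h = mh, snout_v = mv, pole_h = ph, pole_v = pv)
}

#' Render one synthetic stereo frame
#'
#' Draws a list of curves as anti-aliased dark ridges with a Gaussian
#' intensity profile across the projected curve in both views, composites
#' the static dark regions (snout, pole), adds i.i.d. Gaussian pixel noise
#' from the current RNG state, and clips to `[0, 1]`.
#'
#' @param curves List of [bezier3d] curves (possibly empty).
#' @param scene A [scene_config].
#' @param model A [camera_model].
#' @param overlays Precomputed [scene_overlays] (internal; computed when
#'   `NULL`).
#' @param frame Frame index stored in the result.
#' @param render_s Parameter range to render for each curve (defaults to
#'   `scene$render_s`).
#' @return A frame pair: list with `frame`, `h` and `v` image matrices in
#'   `[0, 1]` (rows = `y` / `w`, columns = `x` / `v`, 0-based pixel-centre
#'   coordinates).
#' @export
render_frame_pair <- function(curves, scene, model, overlays = NULL,
                              frame = 1L, render_s = NULL) {
  nr <- scene$image_size[1]; nc <- scene$image_size[2]
  if (is.null(overlays)) overlays <- scene_overlays(scene, model)
  if (is.null(render_s)) render_s <- scene$render_s
  radius <- 4 * scene$ridge_sd
  d2h <- matrix(Inf, nr, nc)
  d2v <- matrix(Inf, nr, nc)
  for (crv in curves) {
    len <- bezier_arc_length(crv, render_s[1], render_s[2])
    ns <- max(16L, ceiling(len / 0.3))
    s <- seq(render_s[1], render_s[2], length.out = ns)
    p3 <- bezier_point(crv, s, extend = TRUE)
    ph <- project_horizontal(p3, model)
    pv <- project_vertical(p3, model)
    cpp_accum_dist2(d2h, ph[, 1], ph[, 2], radius)
    cpp_accum_dist2(d2v, pv[, 1], pv[, 2], radius)
  }
  img_h <- matrix(scene$background, nr, nc)
  img_v <- matrix(scene$background, nr, nc)
  ih <- which(is.finite(d2h))
  iv <- which(is.finite(d2v))
  depth_h <- scene$whisker_contrast * exp(-d2h[ih] / (2 * scene$ridge_sd^2))
  depth_v <- scene$whisker_contrast * exp(-d2v[iv] / (2 * scene$ridge_sd^2))
  img_h[ih] <- pmin(img_h[ih], scene$background - depth_h)
  img_v[iv] <- pmin(img_v[iv], scene$background - depth_v)
  blend <- function(img, mask, dark) {
    if (is.null(mask)) img else img * (1 - mask) + dark * mask
  }
  img_h <- blend(img_h, overlays$snout_h, scene$snout$intensity)
  img_v <- blend(img_v, overlays$snout_v, scene$snout$intensity)
  if (!is.null(scene$pole)) {
    img_h <- blend(img_h, overlays$pole_h, scene$pole$intensity)
    img_v <- blend(img_v, overlays$pole_v, scene$pole$intensity)
  }
  if (scene$noise_sd > 0) {
    img_h <- img_h + matrix(stats::rnorm(nr * nc, 0, scene$noise_sd), nr, nc)
    img_v <- img_v + matrix(stats::rnorm(nr * nc, 0, scene$noise_sd), nr, nc)
  }
  img_h[img_h < 0] <- 0; img_h[img_h > 1] <- 1
  img_v[img_v < 0] <- 0; img_v[img_v > 1] <- 1
  list(frame = frame, h = img_h, v = img_v)
}

in_view <- function(p2, nr, nc) {
  all(p2[, 1] >= 0 & p2[, 1] <= nc - 1 & p2[, 2] >= 0 & p2[, 2] <= nr - 1)
}

#' Generate a synthetic whisking sequence with ground truth
#'
#' Renders `n_frames` stereo frame pairs of one or more whiskers moving
#' according to their [motion_model]s, and records exact ground truth per
#' frame per whisker: the true curve, the true pose angles, and the true 3D
#' curvature at the base. Output is deterministic for a fixed seed.
#'
#' @param scene A [scene_config].
#' @param motions A [motion_model] or list of them.
#' @param n_frames Number of frames (>= 3).
#' @param model A [camera_model].
#' @param seed Integer seed controlling the pixel noise.
#' @return An object of class `whisker_scene`: list with `frames` (list of
#'   frame pairs), `truth` (tibble: `frame`, `whisker_id`, control points,
#'   `theta`, `phi`, `zeta`, `kappa3d` in 1/mm, `out_of_frame`), `scene`,
#'   `model`.
#' @export
generate_whisking_sequence <- function(scene, motions, n_frames,
                                       model = default_camera_model(),
                                       seed = 1) {
  if (n_frames < 3) stop("n_frames must be >= 3")
  if (inherits(motions, "motion_model")) motions <- list(motions)
  overlays <- scene_overlays(scene, model)
  nr <- scene$image_size[1]; nc <- scene$image_size[2]
  local_seed(seed)
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  warned <- FALSE
  for (f in seq_len(n_frames)) {
    states <- purrr::map(motions, motion_state, frame = f, scene = scene)
    curves <- purrr::map(states, "curve")
    rows <- purrr::map2(states, motions, function(st, mo) {
      seg <- bezier_point(st$curve, seq(0, 1, length.out = 16))
      oof <- !(in_view(project_horizontal(seg, model), nr, nc) &&
                 in_view(project_vertical(seg, model), nr, nc))
      tibble::tibble(
        frame = f, whisker_id = mo$whisker_id,
        !!!curve_to_cols(st$curve),
        theta = st$theta, phi = st$phi, zeta = st$zeta,
        kappa3d = st$kappa3d_mm, out_of_frame = oof)
    })
    truth[[f]] <- dplyr::bind_rows(rows)
    if (!warned && any(truth[[f]]$out_of_frame)) {
      warning("whisker segment outside the field of view; truth flagged")
      warned <- TRUE
    }
    frames[[f]] <- render_frame_pair(curves, scene, model, overlays, f)
  }
  structure(list(frames = frames, truth = dplyr::bind_rows(truth),
                 scene = scene, model = model),
            class = "whisker_scene")
}

#' Generate the rigid rotating-edge control sequence
#'
#' Emulates the rigid test object used to validate curvature recovery: a
#' thin circular edge (a 13 mm glass coverslip mounted on a medio-lateral
#' rod) rotated about the rod axis while oscillating in azimuth, so its
#' projected planar curvatures swing strongly while its true 3D shape never
#' changes. The rendered edge segment is the rigid quadratic with 3D
#' curvature `2 / diameter` at the tracked base point, rotated per frame
#' (see the package vignette for why the tracker's own curve family, rather
#' than a resampled circle, is the appropriate rigid phantom; `edge =
#' "circle"` renders the true circular arc instead). A dark mount region
#' beside the base plays the role of the snout for renormalization.
#'
#' @param scene A [scene_config]; its snout settings are overridden by the
#'   mount (use [disk_scene_config()] for suitable defaults).
#' @param diameter_mm Diameter of the circular edge.
#' @param roll_profile,azimuth_profile Per-frame rotation about the rod
#'   (medio-lateral) axis and per-frame azimuth, degrees; equal lengths.
#' @param model A [camera_model].
#' @param segment_mm Arc length of the tracked edge segment.
#' @param edge `"bezier"` (rigid quadratic phantom) or `"circle"` (true
#'   circular arc; its base curvature then differs from the quadratic
#'   model's by a curve-family approximation bias).
#' @param seed Integer seed for the pixel noise.
#' @return A `whisker_scene` (whisker id `"edge"`); truth `kappa3d` is
#'   constant over frames by construction.
#' @export
generate_disk_sequence <- function(scene, diameter_mm = 13,
                                   roll_profile, azimuth_profile,
                                   model = default_camera_model(),
                                   segment_mm = 3.8, edge = "bezier",
                                   seed = 1) {
  stopifnot(diameter_mm > 0,
            length(roll_profile) == length(azimuth_profile))
  n_frames <- length(roll_profile)
  kmm <- 2 / diameter_mm
  kpx <- kmm * scene$pixel_mm
  L <- segment_mm / scene$pixel_mm
  cx <- (scene$image_size[2] - 1) / 2
  base <- c(cx, scene$snout$y0 + 15, (scene$image_size[1] - 1) / 2)
  # canonical segment rotated so the base tangent is +y, bending towards +x
  local <- t(rot_z(pi / 2) %*% diag(c(1, -1, 1)) %*% t(canonical_segment(kpx, L)))
  overlays <- scene_overlays(scene, model)
  nr <- scene$image_size[1]; nc <- scene$image_size[2]
  local_seed(seed)
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    M <- rot_z(azimuth_profile[f] * pi / 180) %*%
      rot_y(roll_profile[f] * pi / 180)
    world <- t(M %*% t(local)) + rep(1, 3) %o% base
    crv <- bezier3d(world[1, ], world[2, ], world[3, ])
    seg <- bezier_point(crv, seq(0, 1, length.out = 16))
    if (!(in_view(project_horizontal(seg, model), nr, nc) &&
            in_view(project_vertical(seg, model), nr, nc)))
      stop("edge segment outside the field of view")
    render_curves <- if (identical(edge, "circle")) {
      list(circle_arc_polyline(base, M, 1 / kpx, L, scene$render_s))
    } else list(crv)
    frames[[f]] <- if (identical(edge, "circle")) {
      render_polyline_frame(render_curves[[1]], scene, model, overlays, f)
    } else {
      render_frame_pair(render_curves, scene, model, overlays, f)
    }
    ang <- pose_angles(whisker_frame(crv))
    truth[[f]] <- tibble::tibble(
      frame = f, whisker_id = "edge", !!!curve_to_cols(crv),
      theta = ang$theta, phi = ang$phi, zeta = ang$zeta,
      kappa3d = curvature3d(crv, 0, scene$pixel_mm), out_of_frame = FALSE)
  }
  structure(list(frames = frames, truth = dplyr::bind_rows(truth),
                 scene = scene, model = model),
            class = "whisker_scene")
}

#' Scene configuration for the rigid-edge control
#'
#' Like [scene_config()] but with the snout replaced by the dark mount
#' region beside the edge's base (dark at low `y` in the horizontal view).
#'
#' @inheritParams scene_config
#' @param ... Passed to [scene_config()].
#' @export
disk_scene_config <- function(...) {
  scene_config(snout = list(enabled = TRUE, y0 = 45, bow = 0,
                            side_h = "low", v0 = 64, v_bow = 0,
                            side_v = "low", intensity = 0.12),
               ...)
}

# 3D polyline of a circular arc matching the rigid quadratic phantom's
# base point, base tangent and base curvature.
circle_arc_polyline <- function(base, M, r_px, L, render_s) {
  u <- seq(render_s[1], render_s[2], length.out = 800) * (L / r_px)
  local <- cbind(r_px * (1 - cos(u)), r_px * sin(u), 0)
  t(M %*% t(local)) + rep(1, length(u)) %o% base
}

# Render a frame pair from an explicit 3D polyline (used for edge = "circle").
render_polyline_frame <- function(pts3, scene, model, overlays, frame) {
  nr <- scene$image_size[1]; nc <- scene$image_size[2]
  radius <- 4 * scene$ridge_sd
  d2h <- matrix(Inf, nr, nc); d2v <- matrix(Inf, nr, nc)
  ph <- project_horizontal(pts3, model)
  pv <- project_vertical(pts3, model)
  cpp_accum_dist2(d2h, ph[, 1], ph[, 2], radius)
  cpp_accum_dist2(d2v, pv[, 1], pv[, 2], radius)
  img_h <- matrix(scene$background, nr, nc)
  img_v <- matrix(scene$background, nr, nc)
  ih <- which(is.finite(d2h)); iv <- which(is.finite(d2v))
  img_h[ih] <- pmin(img_h[ih], scene$background -
                      scene$whisker_contrast *
                      exp(-d2h[ih] / (2 * scene$ridge_sd^2)))
  img_v[iv] <- pmin(img_v[iv], scene$background -
                      scene$whisker_contrast *
                      exp(-d2v[iv] / (2 * scene$ridge_sd^2)))
  if (!is.null(overlays$snout_h)) {
    img_h <- img_h * (1 - overlays$snout_h) +
      scene$snout$intensity * overlays$snout_h
    img_v <- img_v * (1 - overlays$snout_v) +
      scene$snout$intensity * overlays$snout_v
  }
  if (scene$noise_sd > 0) {
    img_h <- img_h + matrix(stats::rnorm(nr * nc, 0, scene$noise_sd), nr, nc)
    img_v <- img_v + matrix(stats::rnorm(nr * nc, 0, scene$noise_sd), nr, nc)
  }
  img_h[img_h < 0] <- 0; img_h[img_h > 1] <- 1
  img_v[img_v < 0] <- 0; img_v[img_v > 1] <- 1
  list(frame = frame, h = img_h, v = img_v)
}

#' Generate a synthetic calibration pin sequence
#'
#' 3D pin positions on a smooth space-filling (Lissajous) path through the
#' tracking volume, projected through the vertical camera with Gaussian
#' pixel noise, as produced by moving a pin object through the set-up while
#' recording corresponding images.
#'
#' @param model A [camera_model] (the true mapping).
#' @param n Number of pin positions.
#' @param noise_px Gaussian observation noise SD on `(v, w)`, px.
#' @param seed Integer seed.
#' @param centre,half_span Centre and half-extent (px) of the volume
#'   explored by the pin path.
#' @return Tibble with columns `frame`, `x`, `y`, `z`, `v`, `w`.
#' @export
generate_calibration_sequence <- function(model = default_camera_model(),
                                          n = 100, noise_px = 0.25,
                                          seed = 1, centre = c(240, 240, 240),
                                          half_span = c(140, 140, 140)) {
  if (n < 4) stop("need at least 4 calibration points")
  local_seed(seed)
  t <- seq(0, 1, length.out = n)
  p3 <- cbind(centre[1] + half_span[1] * sin(2 * pi * 3 * t),
              centre[2] + half_span[2] * sin(2 * pi * 2 * t + 1),
              centre[3] + half_span[3] * sin(2 * pi * 5 * t + 2))
  pv <- project_vertical(p3, model)
  pv <- pv + matrix(stats::rnorm(2 * n, 0, noise_px), n, 2)
  tibble::tibble(frame = seq_len(n), x = p3[, 1], y = p3[, 2], z = p3[, 3],
                 v = pv[, 1], w = pv[, 2])
}

# Seed the RNG for the rest of the calling function, restoring the previous
# state on exit (keeps generators deterministic without clobbering the
# caller's random stream).
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, envir = env)
  invisible()
}
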