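#' Orthographic stereo camera model
#'
#' Both cameras image through telecentric lenses, so each view is an
#' orthographic (affine) projection of the head-centred frame:
#' \deqn{p^H = H p^{3D} + h, \qquad p^V = V p^{3D} + v.}
#' The horizontal view shares its axes and origin with the 3D frame, so `H`
#' is fixed at `[1 0 0; 0 1 0]` and `h = (0, 0)`; only the vertical-view
#' mapping (`V`, `v_off`) is free and is estimated by calibration
#' ([fit_vertical_mapping]).
#'
#' @param V 2x3 matrix mapping 3D points to vertical-image `(v, w)`.
#' @param v_off Length-2 offset vector for the vertical view.
#' @param pixel_mm Pixel pitch in mm/px (default 0.047).
#' @param image_size Integer `(rows, cols)` of both views, used for
#'   bounds checks and rendering.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(V, v_off = c(0, 0), pixel_mm = 0.047,
                         image_size = c(480L, 480L)) {
  V <- matrix(as.numeric(V), 2, 3)
  if (!all(is.finite(V)) || qr(V)$rank < 2)
    stop("V must be a finite rank-2 2x3 matrix")
  structure(
    list(H = matrix(c(1, 0, 0, 1, 0, 0), 2, 3), h = c(0, 0),
         V = V, v_off = as.numeric(v_off), pixel_mm = pixel_mm,
         image_size = as.integer(image_size)),
    class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model> orthographic stereo model\n")
  cat("V:\n"); print(x$V)
  cat("v_off:", format(x$v_off), "\n")
  cat("pixel pitch:", x$pixel_mm, "mm/px; image",
      paste(x$image_size, collapse = "x"), "px\n")
  invisible(x)
}

#' Default synthetic camera model
#'
#' A vertical camera oriented like the experimental one: nominally viewing
#' along the anterior-posterior axis (so `v` tracks medio-lateral position
#' and `w` runs ventral-positive), tilted 25 degrees off the coronal plane
#' and 10 degrees off horizontal to keep whiskers clear of the body. The
#' offset is chosen so the centre of the imaged volume lands at the centre
#' of the vertical image.
#'
#' @inheritParams camera_model
#' @param centre 3D point mapped to the vertical-image centre.
#' @return A [camera_model].
#' @export
default_camera_model <- function(pixel_mm = 0.047,
                                 image_size = c(480L, 480L),
                                 centre = c(240, 240, 240)) {
  Rz <- rot_z(25 * pi / 180)
  Ry <- rot_y(10 * pi / 180)
  e_v <- Ry %*% Rz %*% c(0, 1, 0)   # medial-positive image axis
  e_w <- Ry %*% Rz %*% c(0, 0, -1)  # ventral-positive image axis
  V <- rbind(drop(e_v), drop(e_w))
  v_off <- (image_size[c(2, 1)] - 1) / 2 - drop(V %*% centre)
  camera_model(V, v_off, pixel_mm, image_size)
}

#' Camera model matched to a scene configuration
#'
#' Convenience wrapper building the default vertical-camera geometry with
#' the scene's pixel pitch and image size, centred on the middle of the
#' imaged volume.
#'
#' @param scene A [scene_config].
#' @return A [camera_model].
#' @export
scene_camera <- function(scene) {
  c0 <- (scene$image_size[2] - 1) / 2
  default_camera_model(scene$pixel_mm, scene$image_size,
                       centre = c(c0, c0, c0))
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Project 3D points into the horizontal view
#'
#' The horizontal camera shares axes with the 3D frame, so this simply
#' drops the `z` coordinate.
#'
#' @param p Length-3 vector or n x 3 matrix of 3D points.
#' @param model A [camera_model].
#' @return n x 2 matrix (or length-2 vector) of `(x, y)` image points.
#' @export
project_horizontal <- function(p, model) {
  p <- rbind3(p)
  out <- p[, 1:2, drop = FALSE]   # H = [1 0 0; 0 1 0], h = 0
  colnames(out) <- c("x", "y")
  if (nrow(out) == 1L) drop(out) else out
}

#' Project 3D points into the vertical view
#'
#' @inheritParams project_horizontal
#' @return n x 2 matrix (or length-2 vector) of `(v, w)` image points.
#' @export
project_vertical <- function(p, model) {
  p <- rbind3(p)
  out <- p %*% t(model$V) + rep(1, nrow(p)) %o% model$v_off
  colnames(out) <- c("v", "w")
  if (nrow(out) == 1L) drop(out) else out
}

rbind3 <- function(p) {
  if (is.null(dim(p))) matrix(p, 1, 3) else as.matrix(p)
}

#' Fit the vertical-camera mapping by linear regression
#'
#' Ordinary least squares for the 8 unknowns of `p^V = V p^{3D} + v`
#' (two independent affine rows), from a calibration table of corresponding
#' 3D pin positions and vertical-view image positions. The residual variance
#' is reported as a percentage of the total variance of the observed
#' `(v, w)` coordinates; with the imaging system working correctly this is
#' well under 0.1%.
#'
#' @param calib Data frame with columns `x`, `y`, `z`, `v`, `w`
#'   (pixels; at least 4 rows), e.g. from [generate_calibration_sequence()]
#'   or [read_calibration_pins()].
#' @param pixel_mm,image_size Passed to the returned [camera_model].
#' @return An object of class `whisker_calibration`: a list with the fitted
#'   `model`, `residual_pct` (residual variance as % of total), `n`, and
#'   per-coordinate coefficient table. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_vertical_mapping <- function(calib, pixel_mm = 0.047,
                                 image_size = c(480L, 480L)) {
  calib <- as.data.frame(calib)
  need <- c("x", "y", "z", "v", "w")
  if (!all(need %in% names(calib)))
    stop("calibration table must have columns x, y, z, v, w")
  if (nrow(calib) < 4) stop("need at least 4 calibration points")
  X <- cbind(calib$x, calib$y, calib$z, 1)
  if (qr(X)$rank < 4)
    stop("degenerate calibration geometry: 3D pin positions are rank-deficient ",
         "(e.g. collinear or coplanar along the camera axis)")
  Y <- cbind(calib$v, calib$w)
  beta <- qr.solve(X, Y)                 # 4 x 2, closed-form OLS
  fittedY <- X %*% beta
  res <- Y - fittedY
  total <- sum(scale(Y, scale = FALSE)^2)
  residual_pct <- 100 * sum(res^2) / total
  model <- camera_model(t(beta[1:3, ]), beta[4, ], pixel_mm, image_size)
  structure(
    list(model = model, residual_pct = residual_pct, n = nrow(calib),
         coefficients = tibble::tibble(
           response = rep(c("v", "w"), each = 4),
           term = rep(c("x", "y", "z", "offset"), 2),
           estimate = c(beta[, 1], beta[, 2])),
         rmse = sqrt(mean(res^2))),
    class = "whisker_calibration")
}

#' @export
print.whisker_calibration <- function(x, ...) {
  cat("<whisker_calibration> fitted vertical-camera mapping\n")
  cat(sprintf("  n = %d pins; residual variance %.4g%% of total; RMSE %.4g px\n",
              x$n, x$residual_pct, x$rmse))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy whisker_calibration
#' @export
tidy.whisker_calibration <- function(x, ...) x$coefficients

#' @method glance whisker_calibration
#' @export
glance.whisker_calibration <- function(x, ...) {
  tibble::tibble(n = x$n, residual_pct = x$residual_pct, rmse = x$rmse)
}

#' Epipolar line in the vertical view of a horizontal-view point
#'
#' A point `(x, y)` seen in the horizontal view constrains the 3D point to
#' the vertical line `{(x, y, z): z free}`, whose image under the vertical
#' camera is a straight line (projections are affine). Returned as a point
#' and direction; the direction is the third column of `V`.
#'
#' @param pH Length-2 `(x, y)` point.
#' @param model A [camera_model].
#' @return List with `point` (image of z = 0), `direction` (unnormalised),
#'   and `degenerate` flag (`TRUE` when the z-column of `V` vanishes and the
#'   line collapses to a point).
#' @export
vertical_epipolar_line <- function(pH, model) {
  p0 <- drop(model$V %*% c(pH[1], pH[2], 0)) + model$v_off
  dir <- model$V[, 3]
  list(point = p0, direction = dir,
       degenerate = sqrt(sum(dir^2)) < 1e-12)
}

#' Triangulate a 3D point from its two projections
#'
#' Least-squares solution of the stacked projection equations (4 equations,
#' 3 unknowns, both views weighted equally). The horizontal view pins `x`
#' and `y` almost exactly; the vertical view supplies `z`. The reprojection
#' residual reports any inconsistency between the two observations.
#'
#' @param pH Length-2 `(x, y)` horizontal-view point.
#' @param pV Length-2 `(v, w)` vertical-view point.
#' @param model A [camera_model].
#' @return List with `point` (length-3) and `residual` (reprojection error
#'   norm, px).
#' @export
triangulate <- function(pH, pV, model) {
  A <- rbind(model$H, model$V)
  b <- c(pH - model$h, pV - model$v_off)
  p <- qr.solve(A, b)
  names(p) <- c("x", "y", "z")
  list(point = p, residual = sqrt(sum((A %*% p - b)^2)))
}

#' Write / read a calibration file
#'
#' Calibration is stored as plain-text JSON holding the vertical-camera
#' matrix (row-major), its offset, the pixel pitch and the image size. The
#' horizontal mapping is fixed by convention and not stored.
#'
#' @param model A [camera_model] (or `whisker_calibration`, whose model is
#'   taken).
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly;
#'   `read_calibration` returns a [camera_model].
#' @export
write_calibration <- function(model, path) {
  if (inherits(model, "whisker_calibration")) model <- model$model
  jsonlite::write_json(
    list(V = as.numeric(t(model$V)), v_off = model$v_off,
         pixel_mm = model$pixel_mm, image_size = model$image_size),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_model(matrix(j$V, 2, 3, byrow = TRUE), j$v_off, j$pixel_mm,
               j$image_size)
}

#' Read a calibration pin table
#'
#' CSV with header columns `frame, x, y, z, v, w` (pixels; `z` already
#' converted from stage units via the stage-to-pixel scale).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_calibration_pins <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame", "x", "y", "z", "v", "w")
  if (!all(need %in% names(df)))
    stop("calibration pin file must have columns: ", paste(need, collapse = ", "))
  df
}
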