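#' Quadratic 3D Bezier curve
#'
#' Constructs the curve segment
#' \deqn{b(s) = cp_0 (1-s)^2 + 2 cp_1 (1-s) s + cp_2 s^2, \quad 0 \le s \le 1,}
#' used throughout the package to describe the basal segment of a whisker.
#' `cp0` is the proximal control point (whisker base end, `s = 0`), `cp2` the
#' distal one (`s = 1`) and `cp1` sets the bow of the segment. Coordinates are
#' in the head-centred frame: `x` anterior-posterior (positive posterior),
#' `y` medio-lateral (positive medial), `z` dorso-ventral (positive dorsal),
#' in horizontal-camera pixels.
#'
#' @param cp0,cp1,cp2 Numeric length-3 vectors `(x, y, z)`.
#' @return An object of class `bezier3d`: a 3x3 numeric matrix with one
#'   control point per row.
#' @examples
#' crv <- bezier3d(c(0, 0, 0), c(1, 2, 0), c(2, 0, 0))
#' bezier_point(crv, 0.5)
#' @export
bezier3d <- function(cp0, cp1, cp2) {
  m <- rbind(cp0 = as.numeric(cp0), cp1 = as.numeric(cp1),
             cp2 = as.numeric(cp2))
  if (ncol(m) != 3L) stop("control points must have 3 coordinates (x, y, z)")
  if (!all(is.finite(m))) stop("control points must be finite")
  if (sum((m[3, ] - m[1, ])^2) == 0)
    stop("degenerate curve: cp0 and cp2 coincide (zero chord)")
  colnames(m) <- c("x", "y", "z")
  structure(m, class = "bezier3d")
}

#' @export
print.bezier3d <- function(x, ...) {
  cat("<bezier3d> quadratic 3D Bezier curve (px)\n")
  print(unclass(x))
  invisible(x)
}

is_bezier3d <- function(x) inherits(x, "bezier3d")

as_bezier3d <- function(m) {
  bezier3d(m[1, ], m[2, ], m[3, ])
}

#' Evaluate a Bezier curve
#'
#' @param curve A [bezier3d] curve.
#' @param s Numeric vector of curve parameters in `[0, 1]` (use
#'   `extend = TRUE` to evaluate the underlying parabola outside that range,
#'   e.g. when extrapolating towards the snout).
#' @param extend Allow `s` outside `[0, 1]`.
#' @return A matrix with one row per `s` and columns `x`, `y`, `z`
#'   (a plain vector if `s` has length 1).
#' @export
bezier_point <- function(curve, s, extend = FALSE) {
  if (!extend && any(s < 0 | s > 1))
    stop("s outside [0, 1]; set extend = TRUE to evaluate the extension")
  b0 <- (1 - s)^2
  b1 <- 2 * (1 - s) * s
  b2 <- s^2
  out <- cbind(b0, b1, b2) %*% unclass(curve)
  colnames(out) <- c("x", "y", "z")
  if (length(s) == 1L) drop(out) else out
}

#' First and second derivatives of a Bezier curve
#'
#' For a quadratic, `b'(s) = 2(1-s)(cp1-cp0) + 2s(cp2-cp1)` and
#' `b'' = 2(cp2 - 2 cp1 + cp0)`, constant in `s`.
#'
#' @inheritParams bezier_point
#' @param s Single curve parameter (any real; the quadratic extends).
#' @return List with elements `d1` and `d2`, each a length-3 vector.
#' @export
bezier_derivatives <- function(curve, s = 0) {
  m <- unclass(curve)
  d1 <- 2 * (1 - s) * (m[2, ] - m[1, ]) + 2 * s * (m[3, ] - m[2, ])
  d2 <- 2 * (m[3, ] - 2 * m[2, ] + m[1, ])
  list(d1 = d1, d2 = d2)
}

# Speed of the parameterization |b'(s)|, vectorized over s.
bezier_speed <- function(curve, s) {
  m <- unclass(curve)
  a <- m[2, ] - m[1, ]
  b <- m[3, ] - m[2, ]
  dx <- 2 * ((1 - s) %o% a + s %o% b)
  sqrt(rowSums(dx^2))
}

#' Arc length of a Bezier curve segment
#'
#' Numeric quadrature of `|b'(s)|` between two parameter values, by adaptive
#' Gauss-Kronrod integration to a relative tolerance of 1e-8.
#'
#' @inheritParams bezier_point
#' @param s_from,s_to Parameter interval, `s_from < s_to`. Values outside
#'   `[0, 1]` measure along the natural extension of the parabola.
#' @return Arc length in pixels.
#' @export
bezier_arc_length <- function(curve, s_from = 0, s_to = 1) {
  if (s_from >= s_to) stop("s_from must be < s_to")
  m <- unclass(curve)
  if (all(m[1, ] == m[2, ]) && all(m[2, ] == m[3, ]))
    stop("degenerate curve: all control points equal")
  stats::integrate(function(s) bezier_speed(curve, s),
                   s_from, s_to, rel.tol = 1e-8, abs.tol = 0)$value
}

#' 3D curvature of a Bezier curve
#'
#' The standard space-curve curvature
#' \deqn{\kappa_{3D}(s) = \frac{|b'(s) \times b''(s)|}{|b'(s)|^3},}
#' the reciprocal of the osculating-circle radius. It is invariant to rigid
#' rotation and translation of the curve and so measures intrinsic shape,
#' unlike the planar projections ([curvature_planar]).
#'
#' @inheritParams bezier_derivatives
#' @param pixel_mm Optional pixel pitch (mm per pixel). When supplied, the
#'   curvature is returned in 1/mm instead of 1/pixel.
#' @return Non-negative curvature.
#' @export
curvature3d <- function(curve, s = 0, pixel_mm = NULL) {
  d <- bezier_derivatives(curve, s)
  sp <- sqrt(sum(d$d1^2))
  if (sp < 1e-12) stop("zero tangent: curvature undefined at this s")
  cr <- cross3(d$d1, d$d2)
  k <- sqrt(sum(cr^2)) / sp^3
  if (!is.null(pixel_mm)) k <- k / pixel_mm
  k
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed planar curvature of a Bezier curve projection
#'
#' Curvature of the projection of the curve into the horizontal plane
#' (from the `x`, `y` components) or the head-frame coronal plane
#' (from the `z`, `y` components):
#' \deqn{\kappa_h = \frac{x' y'' - x'' y'}{(x'^2 + y'^2)^{3/2}}, \qquad
#'       \kappa_v = \frac{z' y'' - z'' y'}{(z'^2 + y'^2)^{3/2}}.}
#' Both depend on curve orientation (a rolling whisker changes them while its
#' 3D curvature is constant), which is the central reason for tracking in 3D.
#'
#' @inheritParams curvature3d
#' @param plane `"horizontal"` or `"vertical"`.
#' @param model Optional [camera_model]. When given together with
#'   `image_frame = TRUE` and `plane = "vertical"`, the curvature is computed
#'   from the projected vertical-image coordinates `(v, w)` instead of the
#'   head-frame `(z, y)` components.
#' @param image_frame Use image `(v, w)` coordinates for the vertical plane.
#' @return Signed curvature (1/px, or 1/mm when `pixel_mm` is given).
#' @export
curvature_planar <- function(curve, s = 0,
                             plane = c("horizontal", "vertical"),
                             pixel_mm = NULL, model = NULL,
                             image_frame = FALSE) {
  plane <- match.arg(plane)
  d <- bezier_derivatives(curve, s)
  if (plane == "horizontal") {
    a1 <- d$d1[c("x", "y")]; a2 <- d$d2[c("x", "y")]
  } else if (image_frame) {
    if (is.null(model)) stop("image_frame = TRUE needs a camera model")
    a1 <- drop(model$V %*% d$d1); a2 <- drop(model$V %*% d$d2)
  } else {
    a1 <- d$d1[c("z", "y")]; a2 <- d$d2[c("z", "y")]
  }
  sp2 <- sum(a1^2)
  if (sp2 < 1e-12) stop("zero projected tangent: planar curvature undefined")
  k <- (a1[1] * a2[2] - a2[1] * a1[2]) / sp2^1.5
  if (!is.null(pixel_mm)) k <- k / pixel_mm
  unname(k)
}

#' Reparameterize a quadratic Bezier curve onto a sub- or super-interval
#'
#' Returns the quadratic Bezier curve that traces exactly the point set of
#' the parent parabola restricted to parameter interval
#' `[s_new_start, s_new_end]` (values may lie outside `[0, 1]`; the parabola
#' extends naturally). Shape is preserved exactly: curvature at matched
#' physical points is unchanged. Used by curve renormalization to fix arc
#' length and base position without altering the fitted parabola.
#'
#' @inheritParams bezier_point
#' @param s_new_start,s_new_end New interval endpoints on the parent
#'   parameter scale, `s_new_start < s_new_end`.
#' @return A [bezier3d] curve.
#' @export
bezier_reparam <- function(curve, s_new_start, s_new_end) {
  if (s_new_start >= s_new_end) stop("s_new_start must be < s_new_end")
  p0 <- bezier_point(curve, s_new_start, extend = TRUE)
  p2 <- bezier_point(curve, s_new_end, extend = TRUE)
  # Middle control point from the endpoint tangents: for a quadratic,
  # cp1 = b(s0) + (s1 - s0)/2 * b'(s0).
  d0 <- bezier_derivatives(curve, s_new_start)$d1
  p1 <- p0 + (s_new_end - s_new_start) / 2 * d0
  bezier3d(p0, p1, p2)
}
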