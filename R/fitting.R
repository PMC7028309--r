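#' Regularizer weights
#'
#' Gains of the two priors in the tracking cost: `sigma1` scales the
#' temporal-contiguity term (penalising departure from the motion predicted
#' by linear extrapolation) and `sigma2` the shape-complexity term
#' (penalising migration of the middle control point along the chord).
#' Larger values mean weaker regularisation. Units are px^2. The defaults
#' keep both priors at the few-to-ten percent level of the total cost on
#' the synthetic scenes while making slip-like discontinuities expensive
#' (R1) and pinning the image-degenerate along-chord position of the
#' middle control point (R2). Note that R2 selects a canonical
#' parameterization of the fitted parabola (middle control point over the
#' chord midpoint) rather than altering its shape.
#'
#' @param sigma1,sigma2 Positive gains (px^2).
#' @return An object of class `regularizer_weights`.
#' @export
regularizer_weights <- function(sigma1 = 50, sigma2 = 50) {
  stopifnot(sigma1 > 0, sigma2 > 0)
  structure(list(sigma1 = sigma1, sigma2 = sigma2),
            class = "regularizer_weights")
}

#' Line-integral image cost of a projected curve
#'
#' Mean image intensity along a projected curve,
#' `E = \int_0^1 I(curve(s)) ds`, approximated by the trapezoidal rule over
#' uniformly spaced parameter samples with bilinear interpolation between
#' pixel values. Low when the curve lies on a dark whisker, high on the
#' bright background. Integration is over the curve parameter (not arc
#' length); `weight = "arclength"` switches to arc-length weighting.
#'
#' @param image Image matrix in `[0, 1]`.
#' @param xy n x 2 matrix of projected sample points at uniform `s`
#'   (0-based pixel-centre coordinates; column 1 = image column axis,
#'   column 2 = row axis).
#' @param weight `"parameter"` or `"arclength"`.
#' @return Scalar cost. Errors (class `whisker3d_out_of_frame`) when more
#'   than 25% of the samples fall outside the image; sparser excursions are
#'   sampled at the clamped border position.
#' @export
line_integral_cost <- function(image, xy, weight = "parameter") {
  n <- nrow(xy)
  oob <- mean(xy[, 1] < 0 | xy[, 1] > ncol(image) - 1 |
                xy[, 2] < 0 | xy[, 2] > nrow(image) - 1)
  if (oob > 0.25)
    stop(structure(class = c("whisker3d_out_of_frame", "error", "condition"),
                   list(message = sprintf(
                     "projected curve out of frame (%.0f%% of samples)",
                     100 * oob), call = sys.call(-1))))
  vals <- cpp_bilinear(image, xy[, 1], xy[, 2])
  if (identical(weight, "arclength")) {
    seg <- sqrt(rowSums((xy[-1, , drop = FALSE] -
                           xy[-n, , drop = FALSE])^2))
    sum((vals[-1] + vals[-n]) / 2 * seg) / sum(seg)
  } else {
    (sum(vals) - (vals[1] + vals[n]) / 2) / (n - 1)
  }
}

#' Temporal-contiguity regularizer
#'
#' `R1 = 1/(2 sigma1) * sum_i ||cp_i - cp_hat_i||^2`: penalises control
#' points far from their positions extrapolated from the two previous
#' frames. At 1000 frames/s whisker motion is smooth except at slip events,
#' so this prior keeps each curve locked to its own whisker when several
#' are tracked in parallel.
#'
#' @param cp 3x3 matrix of control points (rows) or [bezier3d].
#' @param cp_hat Extrapolated control points, same layout.
#' @param sigma1 Gain (px^2).
#' @return Scalar penalty.
#' @export
temporal_regularizer <- function(cp, cp_hat, sigma1) {
  sum((unclass(cp) - unclass(cp_hat))^2) / (2 * sigma1)
}

#' Shape-complexity regularizer
#'
#' With chord `q = cp2 - cp0`, penalises the deviation of the along-chord
#' component of the middle control point from the chord midpoint:
#' `R2 = 1/(2 sigma2) * ((cp1 - cp0) . q/|q| - |q|/2)^2`. For near-straight
#' whiskers the middle control point is otherwise ill-determined and tends
#' to migrate towards the base, producing unnatural high-curvature
#' extrapolations; this term pins its along-chord position while leaving
#' the perpendicular (bow) component free.
#'
#' @param cp0,cp1,cp2 Control points (length-3).
#' @param sigma2 Gain (px^2).
#' @return Scalar penalty.
#' @export
shape_regularizer <- function(cp0, cp1, cp2, sigma2) {
  q <- cp2 - cp0
  nq <- sqrt(sum(q^2))
  if (nq < 1e-12) stop("zero chord: shape regularizer undefined")
  dev <- sum((cp1 - cp0) * q) / nq - nq / 2
  dev^2 / (2 * sigma2)
}

#' Extrapolate control points from previous frames
#'
#' Linear extrapolation `cp_hat(f) = 2 cp(f-1) - cp(f-2)`; with a single
#' previous frame the last solution is copied.
#'
#' @param history List of [bezier3d] curves at frames `f-1` (last element)
#'   and optionally `f-2`, most recent last.
#' @return 3x3 matrix of extrapolated control points.
#' @export
extrapolate_controls <- function(history) {
  nh <- length(history)
  if (nh == 0) stop("empty history: nothing to extrapolate from")
  last <- unclass(history[[nh]])
  if (nh == 1) return(last)
  prev <- unclass(history[[nh - 1]])
  2 * last - prev
}

#' Full tracking cost of a curve on one frame
#'
#' `E = Eh + Ev + R1 + R2`: the two image line integrals of the curve's
#' projections plus the two regularizers. This is the objective minimised
#' per frame per whisker.
#'
#' @param frame Frame pair (list with image matrices `h`, `v`).
#' @param curve A [bezier3d] curve.
#' @param cp_hat Extrapolated control points (3x3 matrix) or `NULL` to
#'   omit the temporal term (image + shape only).
#' @param weights A [regularizer_weights].
#' @param model A [camera_model].
#' @param n_samples Integration samples along the curve.
#' @return An object of class `cost_breakdown`: list with `E`, `Eh`, `Ev`,
#'   `R1`, `R2` (`E` is their sum).
#' @export
total_cost <- function(frame, curve, cp_hat, weights, model,
                       n_samples = 64) {
  s <- seq(0, 1, length.out = n_samples)
  p3 <- bezier_point(curve, s)
  Eh <- line_integral_cost(frame$h, project_horizontal(p3, model))
  Ev <- line_integral_cost(frame$v, project_vertical(p3, model))
  m <- unclass(curve)
  R1 <- if (is.null(cp_hat)) 0 else
    temporal_regularizer(m, cp_hat, weights$sigma1)
  R2 <- shape_regularizer(m[1, ], m[2, ], m[3, ], weights$sigma2)
  structure(list(E = Eh + Ev + R1 + R2, Eh = Eh, Ev = Ev, R1 = R1, R2 = R2),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("E = %.5f (Eh %.5f + Ev %.5f + R1 %.5f + R2 %.5f)\n",
              x$E, x$Eh, x$Ev, x$R1, x$R2))
  invisible(x)
}

# Image-evidence cost only (Eh + Ev), with smooth out-of-frame handling for
# use inside the optimizer and template search: clamped border sampling
# plus a penalty proportional to the mean excursion beyond the frame.
image_cost <- function(frame, curve, model, n_samples = 64) {
  s <- seq(0, 1, length.out = n_samples)
  p3 <- bezier_point(curve, s)
  ph <- project_horizontal(p3, model)
  pv <- project_vertical(p3, model)
  trap <- function(vals) (sum(vals) - (vals[1] + vals[length(vals)]) / 2) /
    (length(vals) - 1)
  pen <- function(xy, img) {
    ex <- pmax(0, -xy) + pmax(0, xy - rep(c(ncol(img), nrow(img)) - 1,
                                          each = nrow(xy)))
    mean(ex)
  }
  trap(cpp_bilinear(frame$h, ph[, 1], ph[, 2])) +
    trap(cpp_bilinear(frame$v, pv[, 1], pv[, 2])) +
    0.1 * (pen(ph, frame$h) + pen(pv, frame$v))
}

# Orthonormal basis of the plane normal to a unit vector.
normal_plane_basis <- function(t) {
  ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- cross3(t, ref)
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- cross3(t, n1)
  cbind(n1, n2)
}

#' The 7-parameter fit parameterization
#'
#' The per-frame optimisation varies 7 scalars, not the full 9 control-point
#' coordinates: all 3 components of the middle control point, plus the 2
#' components of `cp0` in the plane normal to the curve tangent at `s = 0`
#' and the 2 components of `cp2` in the plane normal to the tangent at
#' `s = 1` (tangent directions frozen at the seed curve). Sliding of the
#' endpoints along the whisker shaft is thereby excluded from the search
#' space, countering drift of the segment along the whisker, and the
#' parameter count drops from 9 to 7.
#'
#' @param seed A [bezier3d] seed curve.
#' @return List with `n_par` (7), `seed`, the two tangent-normal bases, and
#'   `make_curve(p)` mapping a parameter vector to a curve.
#' @export
fit_parameterization <- function(seed) {
  m <- unclass(seed)
  d0 <- bezier_derivatives(seed, 0)$d1
  d1 <- bezier_derivatives(seed, 1)$d1
  t0 <- d0 / sqrt(sum(d0^2))
  t1 <- d1 / sqrt(sum(d1^2))
  B0 <- normal_plane_basis(t0)
  B2 <- normal_plane_basis(t1)
  make_curve <- function(p) {
    bezier3d(m[1, ] + B0 %*% p[1:2],
             m[2, ] + p[3:5],
             m[3, ] + B2 %*% p[6:7])
  }
  list(n_par = 7L, seed = seed, tangent0 = t0, tangent1 = t1,
       basis0 = B0, basis2 = B2, make_curve = make_curve)
}

#' Fit a Bezier curve to one frame
#'
#' Local quasi-Newton (BFGS) minimisation of the tracking cost
#' ([total_cost]) over the 7-parameter space of [fit_parameterization],
#' with forward-difference numeric gradients (step 1e-3 px), starting at
#' the seed curve. The returned fit never has higher cost than the seed.
#'
#' @param frame Frame pair (list with image matrices `h`, `v`).
#' @param seed Seed [bezier3d] curve (e.g. the extrapolated prediction).
#' @param cp_hat Extrapolated control points for the temporal term (3x3
#'   matrix, or `NULL` to disable it).
#' @param weights A [regularizer_weights].
#' @param model A [camera_model].
#' @param opts List of optimizer options: `max_iter` (default 200), `tol`
#'   (relative cost decrease, 1e-6), `n_samples` (64).
#' @return An object of class `whisker_fit`: list with `curve`, `cost`
#'   (a `cost_breakdown`), `converged`, `iterations`, `seed`.
#' @export
fit_frame <- function(frame, seed, cp_hat, weights, model, opts = list()) {
  o <- utils::modifyList(list(max_iter = 200L, tol = 1e-6, n_samples = 64L),
                         opts)
  par <- fit_parameterization(seed)
  sigma1 <- weights$sigma1
  sigma2 <- weights$sigma2
  fn <- function(p) {
    crv <- par$make_curve(p)
    m <- unclass(crv)
    e <- image_cost(frame, crv, model, o$n_samples)
    if (!is.null(cp_hat))
      e <- e + temporal_regularizer(m, cp_hat, sigma1)
    e <- e + shape_regularizer(m[1, ], m[2, ], m[3, ], sigma2)
    if (!is.finite(e)) stop("non-finite tracking cost")
    e
  }
  res <- stats::optim(rep(0, par$n_par), fn, method = "BFGS",
                      control = list(maxit = o$max_iter, reltol = o$tol,
                                     ndeps = rep(1e-3, par$n_par)))
  fitted <- par$make_curve(res$par)
  structure(list(curve = fitted,
                 cost = total_cost(frame, fitted, cp_hat, weights, model,
                                   o$n_samples),
                 converged = res$convergence == 0,
                 iterations = unname(res$counts["function"]),
                 seed = seed),
            class = "whisker_fit")
}

#' @export
print.whisker_fit <- function(x, ...) {
  cat("<whisker_fit>", if (x$converged) "converged" else "iteration cap",
      "after", x$iterations, "cost evaluations\n")
  print(x$cost)
  invisible(x)
}

# Fixed-order Gauss-Legendre arc length along the parent parabola; exact to
# well below 1e-10 for the smooth quadratic speed function. Used inside
# root finding where adaptive quadrature would be needlessly slow.
gl_nodes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussLegendre(24, -1, 1)
    cache
  }
})

arc_length_gl <- function(curve, a, b) {
  g <- gl_nodes()
  s <- (b - a) / 2 * g$x + (a + b) / 2
  (b - a) / 2 * sum(g$w * bezier_speed(curve, s))
}

#' Extrapolate a curve to its intersection with the snout contour
#'
#' Extends the quadratic to `s < 0` and finds the first crossing of its
#' projection with the snout contour polyline (scanning from the base
#' towards `s = -2`), refined by root bracketing. The returned distance is
#' the 3D arc length from the intersection to `cp0` -- the quantity held
#' constant by curve renormalization so the tracked segment stays anchored
#' to the same part of the whisker.
#'
#' @param curve A [bezier3d] curve.
#' @param contour A [snout_contour].
#' @param model A [camera_model].
#' @param s_min Deepest extrapolation parameter searched (default -2).
#' @return List with `point` (3D position on the parent parabola),
#'   `s` (parameter of the crossing) and `distance` (arc length to `cp0`,
#'   px). Errors (class `whisker3d_no_intersection`) when no crossing
#'   exists in `[s_min, 0]`.
#' @export
extrapolate_to_snout <- function(curve, contour, model, s_min = -2) {
  sgn <- if (identical(contour$side, "high")) 1 else -1
  gap <- function(s) {
    p3 <- bezier_point(curve, s, extend = TRUE)
    p3 <- if (is.null(dim(p3))) matrix(p3, 1) else p3
    p2 <- if (contour$view == "horizontal") {
      project_horizontal(p3, model)
    } else {
      pv <- project_vertical(p3, model)
      if (is.null(dim(pv))) pv <- matrix(pv, 1, 2)
      pv[, c(2, 1), drop = FALSE]     # (w, v): contour value is v(w)
    }
    if (is.null(dim(p2))) p2 <- matrix(p2, 1, 2)
    sgn * (p2[, 2] - contour_at(contour, p2[, 1]))
  }
  sgrid <- seq(0, s_min, length.out = 201)
  gv <- gap(sgrid)
  if (gv[1] >= 0) {   # base already touches / inside the dark region
    return(list(point = bezier_point(curve, 0), s = 0, distance = 0))
  }
  cross_i <- which(gv[-1] >= 0 & gv[-length(gv)] < 0)
  if (length(cross_i) == 0)
    stop(structure(class = c("whisker3d_no_intersection", "error",
                             "condition"),
                   list(message = "no snout intersection in extrapolation range",
                        call = sys.call(-1))))
  i <- cross_i[1]
  root <- stats::uniroot(function(s) gap(s), c(sgrid[i + 1], sgrid[i]),
                         tol = 1e-10)$root
  list(point = bezier_point(curve, root, extend = TRUE), s = root,
       distance = arc_length_gl(curve, root, 0))
}

#' Renormalize a fitted curve to its reference arc length and base distance
#'
#' After convergence the fitted parabola is kept fixed and only the
#' parameter interval is moved (an exact sub/super-segment via
#' [bezier_reparam]): the proximal end is placed so the arc distance from
#' the snout intersection equals the reference base distance, then the
#' distal end so the segment's arc length equals the reference length.
#' Both constraints are met exactly (root finding on the monotone
#' arc-length function) and curve shape is untouched, preventing slow drift
#' of the tracked segment along the whisker shaft. When the extrapolated
#' curve misses the contour the renormalization is skipped and flagged.
#'
#' @param curve Fitted [bezier3d] curve.
#' @param ref_arclength Reference segment arc length (px, > 0).
#' @param ref_base_distance Reference snout-to-`cp0` arc distance (px, >= 0).
#' @param contour A [snout_contour].
#' @param model A [camera_model].
#' @return A [bezier3d] curve with attribute `renormalized` (`FALSE` when
#'   skipped).
#' @export
renormalize_curve <- function(curve, ref_arclength, ref_base_distance,
                              contour, model) {
  stopifnot(ref_arclength > 0, ref_base_distance >= 0)
  hit <- tryCatch(extrapolate_to_snout(curve, contour, model),
                  whisker3d_no_intersection = function(e) NULL)
  if (is.null(hit)) {
    attr(curve, "renormalized") <- FALSE
    return(curve)
  }
  s_int <- hit$s
  f0 <- function(s0) arc_length_gl(curve, s_int, s0) - ref_base_distance
  hi <- 1
  while (f0(hi) < 0 && hi < 8) hi <- hi * 2
  s0 <- stats::uniroot(f0, c(s_int, hi), tol = 1e-12)$root
  f1 <- function(s1) arc_length_gl(curve, s0, s1) - ref_arclength
  hi <- s0 + 1
  while (f1(hi) < 0 && hi < s0 + 16) hi <- hi + 1
  s1 <- stats::uniroot(f1, c(s0 + 1e-9, hi), tol = 1e-12)$root
  out <- bezier_reparam(curve, s0, s1)
  attr(out, "renormalized") <- TRUE
  out
}
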