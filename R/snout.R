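#' Snout contour object
#'
#' The detected (or analytically specified) boundary of the dark snout
#' region in one view, as a function of the along-contour image coordinate:
#' in the horizontal view the contour ordinate `y(x)` per column `x`; in
#' the vertical view the contour abscissa `v(w)` per row `w`. `side` says
#' on which side of the contour the dark region lies (`"high"` = larger
#' coordinate values).
#'
#' @param view `"horizontal"` or `"vertical"`.
#' @param coord Along-contour coordinates (0-based pixel columns/rows).
#' @param value Contour position per coordinate (may contain `NA`).
#' @param valid Logical validity mask (defaults to `!is.na(value)`).
#' @param side `"high"` or `"low"`.
#' @return An object of class `snout_contour`.
#' @export
snout_contour <- function(view = c("horizontal", "vertical"), coord, value,
                          valid = NULL, side = "high") {
  view <- match.arg(view)
  if (is.null(valid)) valid <- !is.na(value)
  structure(list(view = view, coord = as.numeric(coord),
                 value = as.numeric(value), valid = valid, side = side),
            class = "snout_contour")
}

#' @export
print.snout_contour <- function(x, ...) {
  cat(sprintf("<snout_contour> %s view; %d/%d positions valid; dark side %s\n",
              x$view, sum(x$valid), length(x$coord), x$side))
  invisible(x)
}

# Interpolated contour position at arbitrary along-contour coordinates.
contour_at <- function(contour, at) {
  ok <- contour$valid
  stats::approx(contour$coord[ok], contour$value[ok], xout = at,
                rule = 2)$y
}

#' Detect the snout contour in one view
#'
#' Fine image structure (fur, whiskers) is removed by 5x5 median filtering
#' followed by Gaussian smoothing (SD 12 px), then the directional gradient
#' approximately normal to the expected contour is taken and the contour
#' placed at its extremum per column (horizontal view: `y` per `x`) or per
#' row (vertical view: `v` per `w`) -- the strongest bright-to-dark
#' transition, with 3-point parabolic sub-pixel refinement. Positions whose
#' extremum is weaker than `floor_mult` times the robust noise level
#' (median absolute deviation) of the gradient field are masked invalid.
#'
#' @param image Image matrix in `[0, 1]`, at least 64x64.
#' @param view `"horizontal"` or `"vertical"`.
#' @param side Which side of the contour is dark (`"high"`: larger
#'   `y`/`v`).
#' @param median_size Median filter window (px, odd).
#' @param gauss_sd Gaussian smoothing SD (px).
#' @param floor_mult Contrast floor in robust-noise units.
#' @return A [snout_contour].
#' @export
detect_snout_contour <- function(image, view = c("horizontal", "vertical"),
                                 side = "high", median_size = 5,
                                 gauss_sd = 12, floor_mult = 5) {
  view <- match.arg(view)
  if (nrow(image) < 64 || ncol(image) < 64)
    stop("image too small for snout detection (need >= 64x64)")
  stopifnot(median_size >= 1, gauss_sd > 0)
  sm <- EBImage::medianFilter(image, (median_size - 1) / 2)
  sm <- EBImage::gblur(sm, sigma = gauss_sd)
  sm <- as.matrix(sm)
  # work with profiles along the search axis in the columns of P
  P <- if (view == "horizontal") sm else t(sm)
  n <- nrow(P)
  grad <- (P[c(2:n, n), ] - P[c(1, 1:(n - 1)), ]) / 2  # central differences
  sgn <- if (identical(side, "high")) -1 else 1        # bright -> dark
  g <- sgn * grad
  g[c(1, 2, n - 1, n), ] <- -Inf                       # boundary rows masked
  idx <- apply(g, 2, which.max)
  peak <- g[cbind(idx, seq_len(ncol(g)))]
  # robust noise level of the gradient: second differences along the
  # search axis remove the (heavily smoothed, hence locally linear) edge
  # response and retain pixel-scale noise
  gi <- grad[2:(n - 1), , drop = FALSE]
  d2 <- grad[3:n, , drop = FALSE] - 2 * gi + grad[1:(n - 2), , drop = FALSE]
  noise <- stats::mad(d2[is.finite(d2)]) / sqrt(6)
  valid <- is.finite(peak) & peak >= pmax(floor_mult * noise, 1e-6) &
    idx > 2 & idx < n - 1
  # parabolic sub-pixel refinement around the peak
  pos <- rep(NA_real_, ncol(g))
  for (j in which(valid)) {
    i <- idx[j]
    y0 <- g[i - 1, j]; y1 <- g[i, j]; y2 <- g[i + 1, j]
    den <- y0 - 2 * y1 + y2
    off <- if (abs(den) > 1e-12) 0.5 * (y0 - y2) / den else 0
    pos[j] <- (i - 1) + max(-0.5, min(0.5, off))       # 0-based
  }
  if (mean(valid) < 0.5)
    stop("snout detection failed: fewer than half of the image ",
         if (view == "horizontal") "columns" else "rows",
         " show a contour-like gradient extremum")
  snout_contour(view, 0:(ncol(P) - 1), pos, valid, side)
}
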