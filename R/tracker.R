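#' Tracker configuration
#'
#' @param threshold Lock threshold on the total cost `E`; a fitted curve
#'   with `E` above it is declared lost for that frame. `NULL` uses the
#'   per-whisker threshold estimated at initialization (mean on-whisker
#'   image cost plus 5 robust SDs; see [estimate_lock_threshold()]).
#' @param direction `"forward"` or `"backward"` tracking through the
#'   sequence.
#' @param reacq_window Number of frames over which re-acquisition of a lost
#'   whisker is attempted before it is abandoned to manual curation.
#' @param template_stride Template sampling stride for
#'   [auto_initialize()] (every n-th frame of the template track).
#' @param template_range Half-range (px) of the integer translation search
#'   in `x` and `z` used by template matching and re-acquisition.
#' @param weights A [regularizer_weights].
#' @param n_samples,max_iter,tol Optimizer options passed to [fit_frame()].
#' @param snout List: `enabled` (detect the contour and renormalize each
#'   frame), `side_h` (dark side of the horizontal-view contour),
#'   `gauss_sd`, `median_size` (detection parameters).
#' @param renormalize Renormalize accepted fits to the reference arc length
#'   and base distance.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(threshold = NULL, direction = "forward",
                           reacq_window = 50, template_stride = 5,
                           template_range = 5,
                           weights = regularizer_weights(),
                           n_samples = 64, max_iter = 200, tol = 1e-6,
                           snout = list(enabled = TRUE, side_h = "high",
                                        gauss_sd = 12, median_size = 5),
                           renormalize = TRUE) {
  stopifnot(is.null(threshold) || threshold > 0, template_stride >= 1)
  structure(list(threshold = threshold, direction = direction,
                 reacq_window = reacq_window,
                 template_stride = template_stride,
                 template_range = template_range, weights = weights,
                 n_samples = n_samples, max_iter = max_iter, tol = tol,
                 snout = snout, renormalize = renormalize),
            class = "tracker_config")
}

#' Estimate the lock threshold from an on-whisker fit
#'
#' Samples the image intensity along a fitted curve in both views and
#' returns `2 * (mean + 5 * SD)` of the pooled samples -- an estimate of
#' the largest total image cost (`Eh + Ev`) a correctly locked curve
#' should produce, used as the default threshold separating "tracked"
#' from "lost".
#'
#' @param frame Frame pair.
#' @param curve Fitted on-whisker [bezier3d] curve.
#' @param model A [camera_model].
#' @param n_samples Samples along the curve.
#' @return Scalar threshold in cost units.
#' @export
estimate_lock_threshold <- function(frame, curve, model, n_samples = 64) {
  s <- seq(0, 1, length.out = n_samples)
  p3 <- bezier_point(curve, s)
  ph <- project_horizontal(p3, model)
  pv <- project_vertical(p3, model)
  pooled <- c(cpp_bilinear(frame$h, ph[, 1], ph[, 2]),
              cpp_bilinear(frame$v, pv[, 1], pv[, 2]))
  2 * (mean(pooled) + 5 * stats::sd(pooled))
}

#' Initialize a whisker from user-specified control points
#'
#' The manual-equivalent initialization: three `(x, y)` positions clicked
#' in the horizontal view and, for each, a `(v, w)` position marking where
#' the corresponding epipolar line crosses the whisker in the vertical
#' view. Each vertical click is projected onto its epipolar line, the 3D
#' control point triangulated, and the resulting curve refined by a frame
#' fit. Reference arc length and snout base distance are computed from the
#' refined curve and stored for renormalization during tracking.
#'
#' @param clicks_h 3x2 matrix of `(x, y)` clicks, proximal to distal.
#' @param clicks_v 3x2 matrix of `(v, w)` clicks in the same order.
#' @param frame First frame pair.
#' @param model A [camera_model].
#' @param config A [tracker_config].
#' @return An object of class `whisker_init`: list with `curve`,
#'   `ref_arclength`, `ref_base_distance` (`NA` when the snout is not
#'   found/enabled), `threshold`, and the initial `fit`.
#' @export
manual_initialize <- function(clicks_h, clicks_v, frame, model,
                              config = tracker_config()) {
  clicks_h <- as.matrix(clicks_h); clicks_v <- as.matrix(clicks_v)
  stopifnot(nrow(clicks_h) == 3, nrow(clicks_v) == 3)
  cps <- matrix(0, 3, 3)
  for (i in 1:3) {
    line <- vertical_epipolar_line(clicks_h[i, ], model)
    d <- line$direction / sqrt(sum(line$direction^2))
    proj <- line$point + sum((clicks_v[i, ] - line$point) * d) * d
    off_line <- sqrt(sum((clicks_v[i, ] - proj)^2))
    tri <- triangulate(clicks_h[i, ], proj, model)
    if (off_line > 3 || tri$residual > 3)
      stop("inconsistent clicks: vertical-view point ", i, " lies ",
           format(off_line, digits = 3),
           " px from the epipolar line of its horizontal-view point")
    cps[i, ] <- tri$point
  }
  seed <- bezier3d(cps[1, ], cps[2, ], cps[3, ])
  fit <- fit_frame(frame, seed, unclass(seed), config$weights, model,
                   list(max_iter = config$max_iter, tol = config$tol,
                        n_samples = config$n_samples))
  finalize_init(fit, frame, model, config)
}

finalize_init <- function(fit, frame, model, config) {
  crv <- fit$curve
  ref_len <- bezier_arc_length(crv)
  ref_base <- NA_real_
  if (isTRUE(config$snout$enabled)) {
    contour <- tryCatch(
      detect_snout_contour(frame$h, "horizontal", side = config$snout$side_h,
                           median_size = config$snout$median_size,
                           gauss_sd = config$snout$gauss_sd),
      error = function(e) NULL)
    if (!is.null(contour)) {
      hit <- tryCatch(extrapolate_to_snout(crv, contour, model),
                      whisker3d_no_intersection = function(e) NULL)
      if (!is.null(hit)) ref_base <- hit$distance
    }
  }
  thr <- config$threshold
  if (is.null(thr)) thr <- estimate_lock_threshold(frame, crv, model,
                                                   config$n_samples)
  structure(list(curve = crv, ref_arclength = ref_len,
                 ref_base_distance = ref_base, threshold = thr, fit = fit),
            class = "whisker_init")
}

#' Initialize a whisker by template matching against a tracked video
#'
#' Takes the solved curves of a previously tracked whisker (every
#' `template_stride`-th frame), evaluates the image-only cost of each on
#' the first frame of the new video, picks the best (ties resolved to the
#' earliest frame), refines it over integer translations of up to
#' `template_range` px along `x` and `z`, and finishes with a frame fit.
#'
#' @param first_frame First frame pair of the new video.
#' @param template_track `whisker_tracks` rows for one whisker of the
#'   template video.
#' @param model A [camera_model].
#' @param config A [tracker_config].
#' @return A `whisker_init` (as [manual_initialize()]). Errors when the
#'   best refined cost exceeds the lock threshold (no template matches).
#' @export
auto_initialize <- function(first_frame, template_track, model,
                            config = tracker_config()) {
  tt <- template_track[template_track$status %in% c("tracked", "curated"), ]
  if (nrow(tt) == 0) stop("template track has no tracked frames")
  tt <- tt[order(tt$frame), ]
  pick <- tt[seq(1, nrow(tt), by = config$template_stride), ]
  # rank every template by its best cost over the +/- range translation
  # grid: template poses several pixels off the target image as pure
  # background, so untranslated costs cannot discriminate between them
  refined <- purrr::map(seq_len(nrow(pick)), function(i) {
    cand <- translate_search(first_frame, track_row_curve(pick[i, ]),
                             model, config)
    list(curve = cand,
         cost = image_cost(first_frame, cand, model, config$n_samples))
  })
  costs <- purrr::map_dbl(refined, "cost")
  shifted <- refined[[which.min(costs)]]$curve  # which.min: earliest tie
  fit <- fit_frame(first_frame, shifted, unclass(shifted), config$weights,
                   model, list(max_iter = config$max_iter, tol = config$tol,
                               n_samples = config$n_samples))
  init <- finalize_init(fit, first_frame, model, config)
  if (!is.null(config$threshold) &&
        init$fit$cost$Eh + init$fit$cost$Ev > config$threshold)
    stop("no template match: best refined cost exceeds the lock threshold")
  # independent sanity check: a matched whisker must image dark in BOTH
  # views, well below the local background level
  if (init$fit$cost$Eh > 0.6 * stats::median(first_frame$h) ||
        init$fit$cost$Ev > 0.6 * stats::median(first_frame$v))
    stop("no template match: refined template still lies on background ",
         "in at least one view")
  init
}

# Integer translation search along x and z around a curve.
translate_search <- function(frame, curve, model, config,
                             anchor = NULL, weights = NULL) {
  rng <- -config$template_range:config$template_range
  best <- curve; best_cost <- Inf
  m <- unclass(curve)
  for (dx in rng) for (dz in rng) {
    shift <- c(dx, 0, dz)
    cand <- bezier3d(m[1, ] + shift, m[2, ] + shift, m[3, ] + shift)
    cost <- image_cost(frame, cand, model, config$n_samples)
    if (cost < best_cost) { best_cost <- cost; best <- cand }
  }
  best
}

#' Track whiskers through a stereo video
#'
#' The per-frame loop of the tracker. For each frame (forward or backward)
#' and each whisker independently: predict the control points by linear
#' extrapolation from the previous two solutions, fit the curve to the
#' image data ([fit_frame]), accept the fit as `tracked` when its total
#' cost stays below the whisker's lock threshold (then renormalize it to
#' the reference arc length and snout distance), otherwise mark the frame
#' `lost` and attempt re-acquisition on subsequent frames within the
#' re-acquisition window by an integer translation search around the last
#' accepted solution.
#'
#' @param frames List of frame pairs (each a list with `h`, `v`), or a
#'   `whisker_scene` from the synthetic generator.
#' @param init A `whisker_init` or list of them (one per whisker), e.g.
#'   from [manual_initialize()] / [auto_initialize()] / [init_from_truth()].
#' @param config A [tracker_config].
#' @param model A [camera_model].
#' @return A `whisker_tracks` tibble: one row per frame per whisker with
#'   the fitted control points, the cost breakdown and a status flag
#'   (`tracked`, `lost`, `curated`); per-whisker references available via
#'   [track_references()].
#' @export
track_video <- function(frames, init, config = tracker_config(),
                        model = default_camera_model()) {
  if (inherits(frames, "whisker_scene")) {
    if (missing(model) || is.null(model)) model <- frames$model
    frames <- frames$frames
  }
  if (inherits(init, "whisker_init")) init <- list(init)
  n <- length(frames)
  nw <- length(init)
  ids <- names(init)
  if (is.null(ids)) ids <- paste0("w", seq_len(nw))
  order_idx <- if (identical(config$direction, "backward")) n:1 else 1:n
  opts <- list(max_iter = config$max_iter, tol = config$tol,
               n_samples = config$n_samples)
  state <- purrr::map(init, function(ini) list(
    history = list(ini$curve), lost_for = 0L, last_good = ini$curve,
    thr = ini$threshold, ref_len = ini$ref_arclength,
    ref_base = ini$ref_base_distance))
  rows <- vector("list", n * nw)
  ri <- 0L
  for (step in seq_along(order_idx)) {
    f_idx <- order_idx[step]
    frame <- frames[[f_idx]]
    contour <- NULL
    if (isTRUE(config$snout$enabled))
      contour <- tryCatch(
        detect_snout_contour(frame$h, "horizontal",
                             side = config$snout$side_h,
                             median_size = config$snout$median_size,
                             gauss_sd = config$snout$gauss_sd),
        error = function(e) NULL)
    for (wi in seq_len(nw)) {
      st <- state[[wi]]
      if (step == 1) {
        # the initialization frame: record the init fit directly
        cost <- total_cost(frame, st$history[[1]], unclass(st$history[[1]]),
                           config$weights, model, config$n_samples)
        ri <- ri + 1L
        rows[[ri]] <- track_row(f_idx, ids[wi], st$history[[1]], cost,
                                "tracked")
        next
      }
      if (st$lost_for > 0) {
        # re-acquisition mode
        if (st$lost_for > config$reacq_window) {
          ri <- ri + 1L
          rows[[ri]] <- track_row(f_idx, ids[wi], st$last_good,
                                  NULL, "lost")
          state[[wi]]$lost_for <- st$lost_for + 1L
          next
        }
        seedc <- translate_search(frame, st$last_good, model, config)
        fit <- fit_frame(frame, seedc, unclass(st$last_good),
                         config$weights, model, opts)
      } else {
        cp_hat <- extrapolate_controls(st$history)
        seedc <- tryCatch(as_bezier3d(cp_hat), error = function(e) NULL)
        if (is.null(seedc)) seedc <- st$history[[length(st$history)]]
        fit <- fit_frame(frame, seedc, cp_hat, config$weights, model, opts)
      }
      accepted <- fit$cost$E <= st$thr
      if (accepted) {
        crv <- fit$curve
        if (isTRUE(config$renormalize) && !is.null(contour) &&
              is.finite(st$ref_base)) {
          crv <- renormalize_curve(crv, st$ref_len, st$ref_base, contour,
                                   model)
        }
        cp_hat_used <- if (st$lost_for > 0) unclass(st$last_good) else
          extrapolate_controls(st$history)
        cost <- total_cost(frame, crv, cp_hat_used, config$weights, model,
                           config$n_samples)
        if (cost$E > st$thr) {     # renormalization degraded the fit
          crv <- fit$curve
          cost <- fit$cost
        }
        hist <- st$history
        if (st$lost_for > 0) hist <- list()   # restart temporal history
        hist <- c(hist, list(crv))
        if (length(hist) > 2) hist <- hist[(length(hist) - 1):length(hist)]
        st$history <- hist
        st$lost_for <- 0L
        st$last_good <- crv
        state[[wi]] <- st
        ri <- ri + 1L
        rows[[ri]] <- track_row(f_idx, ids[wi], crv, cost, "tracked")
      } else {
        state[[wi]]$lost_for <- st$lost_for + 1L
        ri <- ri + 1L
        rows[[ri]] <- track_row(f_idx, ids[wi], fit$curve, fit$cost, "lost")
      }
    }
  }
  out <- dplyr::bind_rows(rows[seq_len(ri)]) |> dplyr::arrange(.data$frame)
  refs <- tibble::tibble(
    whisker_id = ids,
    ref_arclength = purrr::map_dbl(init, "ref_arclength"),
    ref_base_distance = purrr::map_dbl(init, "ref_base_distance"),
    threshold = purrr::map_dbl(state, "thr"))
  new_whisker_tracks(out, refs)
}

track_row <- function(frame, id, curve, cost, status) {
  if (is.null(cost))
    cost <- list(E = NA_real_, Eh = NA_real_, Ev = NA_real_,
                 R1 = NA_real_, R2 = NA_real_)
  tibble::tibble(frame = frame, whisker_id = id, !!!curve_to_cols(curve),
                 E = cost$E, Eh = cost$Eh, Ev = cost$Ev, R1 = cost$R1,
                 R2 = cost$R2, status = status)
}

#' Initialize directly from a ground-truth table
#'
#' Builds initialization objects (curve, references, threshold) from the
#' synthetic ground truth of the first frame -- the scripted equivalent of
#' clicking exactly on the rendered whiskers. The truth curve is refined by
#' a frame fit exactly as manual clicks would be.
#'
#' @param scene A `whisker_scene`.
#' @param config A [tracker_config].
#' @param refine Refine the truth curves by [fit_frame()] before computing
#'   references (as manual initialization does).
#' @return Named list of `whisker_init` objects, one per whisker.
#' @export
init_from_truth <- function(scene, config = tracker_config(),
                            refine = TRUE) {
  first <- scene$frames[[1]]
  t1 <- scene$truth[scene$truth$frame == min(scene$truth$frame), ]
  inits <- purrr::map(seq_len(nrow(t1)), function(i) {
    crv <- track_row_curve(t1[i, ])
    fit <- if (refine) {
      fit_frame(first, crv, unclass(crv), config$weights, scene$model,
                list(max_iter = config$max_iter, tol = config$tol,
                     n_samples = config$n_samples))
    } else {
      structure(list(curve = crv,
                     cost = total_cost(first, crv, unclass(crv),
                                       config$weights, scene$model,
                                       config$n_samples),
                     converged = TRUE, iterations = 0L, seed = crv),
                class = "whisker_fit")
    }
    finalize_init(fit, first, scene$model, config)
  })
  names(inits) <- t1$whisker_id
  inits
}

#' Replace a tracked frame by a curated solution
#'
#' The programmatic equivalent of nudging control points in a GUI: the
#' curve at one frame is replaced and flagged `curated`. Downstream frames
#' can then be re-tracked from the curated solution with [retrack()].
#'
#' @param tracks A `whisker_tracks` tibble.
#' @param whisker_id Whisker to curate.
#' @param frame Frame index to replace.
#' @param curve The corrected [bezier3d] curve.
#' @return The modified `whisker_tracks`.
#' @export
curate <- function(tracks, whisker_id, frame, curve) {
  if (!is_bezier3d(curve)) curve <- as_bezier3d(as.matrix(curve))
  i <- which(tracks$whisker_id == whisker_id & tracks$frame == frame)
  if (length(i) != 1)
    stop("frame ", frame, " for whisker ", whisker_id, " is not in the track")
  cols <- curve_to_cols(curve)
  for (cc in names(cols)) tracks[[cc]][i] <- cols[[cc]]
  tracks$status[i] <- "curated"
  tracks$E[i] <- NA_real_; tracks$Eh[i] <- NA_real_
  tracks$Ev[i] <- NA_real_; tracks$R1[i] <- NA_real_
  tracks$R2[i] <- NA_real_
  tracks
}

#' Re-track a whisker from a given frame onward
#'
#' Restarts automatic tracking of one whisker from the solution stored at
#' `from_frame` (typically just curated), replacing all downstream rows.
#'
#' @param tracks A `whisker_tracks` tibble with references.
#' @param frames The frame-pair list (or `whisker_scene`) the tracks came
#'   from.
#' @param whisker_id Whisker to re-track.
#' @param from_frame Frame holding the trusted solution.
#' @param config A [tracker_config].
#' @param model A [camera_model].
#' @return The updated `whisker_tracks`.
#' @export
retrack <- function(tracks, frames, whisker_id, from_frame,
                    config = tracker_config(),
                    model = default_camera_model()) {
  if (inherits(frames, "whisker_scene")) {
    model <- frames$model
    frames <- frames$frames
  }
  refs <- track_references(tracks)
  i <- which(tracks$whisker_id == whisker_id & tracks$frame == from_frame)
  if (length(i) != 1) stop("from_frame not found for this whisker")
  ini <- structure(list(
    curve = track_row_curve(tracks[i, ]),
    ref_arclength = refs$ref_arclength[refs$whisker_id == whisker_id],
    ref_base_distance = refs$ref_base_distance[refs$whisker_id == whisker_id],
    threshold = refs$threshold[refs$whisker_id == whisker_id],
    fit = NULL), class = "whisker_init")
  sub <- frames[from_frame:length(frames)]
  new <- track_video(sub, stats::setNames(list(ini), whisker_id), config,
                     model)
  new$frame <- new$frame + from_frame - 1L
  keep_status <- tracks$status[i]
  drop <- tracks$whisker_id == whisker_id & tracks$frame >= from_frame
  out <- dplyr::bind_rows(tracks[!drop, ], new) |>
    dplyr::arrange(.data$frame, .data$whisker_id)
  j <- which(out$whisker_id == whisker_id & out$frame == from_frame)
  out$status[j] <- keep_status
  new_whisker_tracks(out, refs)
}
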