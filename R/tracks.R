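#' @importFrom rlang .data
NULL

track_columns <- c("frame", "whisker_id",
                   "cp0x", "cp0y", "cp0z", "cp1x", "cp1y", "cp1z",
                   "cp2x", "cp2y", "cp2z",
                   "E", "Eh", "Ev", "R1", "R2", "status")

# One track-table row -> bezier3d curve.
track_row_curve <- function(row) {
  bezier3d(c(row$cp0x, row$cp0y, row$cp0z),
           c(row$cp1x, row$cp1y, row$cp1z),
           c(row$cp2x, row$cp2y, row$cp2z))
}

curve_to_cols <- function(curve) {
  m <- unclass(curve)
  out <- as.list(c(m[1, ], m[2, ], m[3, ]))
  names(out) <- track_columns[3:11]
  out
}

new_whisker_tracks <- function(df, references = NULL) {
  df <- tibble::as_tibble(df)
  attr(df, "references") <- references
  class(df) <- c("whisker_tracks", class(df))
  df
}

#' Track references (arc length, base distance, lock threshold)
#'
#' @param tracks A `whisker_tracks` tibble.
#' @return Tibble with one row per whisker: `whisker_id`, `ref_arclength`,
#'   `ref_base_distance`, `threshold`, or `NULL` when the table was read
#'   from disk without them.
#' @export
track_references <- function(tracks) attr(tracks, "references")

#' Per-whisker tracking summary
#'
#' @param x A `whisker_tracks` tibble.
#' @param ... Unused.
#' @return Tibble with lock rate and cost summaries per whisker.
#' @method glance whisker_tracks
#' @export
glance.whisker_tracks <- function(x, ...) {
  x |>
    dplyr::group_by(.data$whisker_id) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      lock_rate = mean(.data$status %in% c("tracked", "curated")),
      mean_E = mean(.data$E[.data$status %in% c("tracked", "curated")]),
      n_lost = sum(.data$status == "lost"),
      .groups = "drop")
}

#' Plot tracked curves projected into both views
#'
#' Shows the horizontal and vertical projections of all tracked curves,
#' coloured by whisker, over a subsample of frames.
#'
#' @param object A `whisker_tracks` tibble.
#' @param model A [camera_model] for the vertical projection.
#' @param every Plot every `every`-th frame.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot whisker_tracks
#' @export
autoplot.whisker_tracks <- function(object, model = default_camera_model(),
                                    every = 10, ...) {
  keep <- object[object$status %in% c("tracked", "curated") &
                   (object$frame %% every == 0 | object$frame == 1), ]
  s <- seq(0, 1, length.out = 25)
  pts <- purrr::map_dfr(seq_len(nrow(keep)), function(i) {
    row <- keep[i, ]
    p3 <- bezier_point(track_row_curve(row), s)
    ph <- project_horizontal(p3, model)
    pv <- project_vertical(p3, model)
    tibble::tibble(
      frame = row$frame, whisker_id = row$whisker_id,
      view = rep(c("horizontal", "vertical"), each = length(s)),
      u = c(ph[, 1], pv[, 1]), w = c(ph[, 2], pv[, 2]),
      piece = paste(row$whisker_id, row$frame))
  })
  ggplot2::ggplot(pts, ggplot2::aes(.data$u, .data$w, group = .data$piece,
                                    colour = factor(.data$whisker_id))) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::facet_wrap(~view) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x / v (px)", y = "y / w (px)", colour = "whisker") +
    ggplot2::theme_minimal()
}

#' Write / read a track table
#'
#' Tracks are stored as plain CSV with one row per frame per whisker and
#' columns `frame, whisker_id, cp0x..cp2z, E, Eh, Ev, R1, R2, status`.
#' Numeric values are written with full round-trip precision, so a
#' write-read cycle reproduces the curves bit for bit. Unknown extra
#' columns are ignored with a warning on read.
#'
#' @param tracks A `whisker_tracks` tibble.
#' @param path CSV path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` a
#'   `whisker_tracks` tibble.
#' @export
write_tracks <- function(tracks, path) {
  out <- tracks[, track_columns]
  # 17 significant digits guarantee an exact double round trip
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x)
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x)))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  # base read.csv: exact (correctly rounded) double parsing, so written
  # 17-digit values reproduce the original binary doubles
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- tibble::as_tibble(df)
  if ("whisker_id" %in% names(df))
    df$whisker_id <- as.character(df$whisker_id)
  for (cc in intersect(track_columns[3:16], names(df)))
    df[[cc]] <- as.numeric(df[[cc]])
  missing <- setdiff(track_columns, names(df))
  if (length(missing) > 0)
    stop("track file is missing columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), track_columns)
  if (length(extra) > 0) {
    warning("ignoring unknown track columns: ", paste(extra, collapse = ", "))
    df <- df[, track_columns]
  }
  new_whisker_tracks(df)
}

#' Compare tracks against ground truth
#'
#' Joins a track table with a synthetic ground-truth table and summarises,
#' per whisker: lock rate, control-point RMSE over locked frames, and RMS
#' errors of the recovered azimuth/elevation/roll angles.
#'
#' @param tracks A `whisker_tracks` tibble.
#' @param truth A ground-truth tibble (see [generate_whisking_sequence()]).
#' @param pixel_mm Pixel pitch used for curvature comparison.
#' @return Tibble with one row per whisker.
#' @export
eval_tracks <- function(tracks, truth, pixel_mm = 0.047) {
  truth <- dplyr::mutate(truth, whisker_id = as.character(.data$whisker_id))
  tracks <- dplyr::mutate(tracks, whisker_id = as.character(.data$whisker_id))
  j <- dplyr::inner_join(tracks, truth, by = c("frame", "whisker_id"),
                         suffix = c("", ".true"))
  pose <- pose_series(tracks) |>
    dplyr::select("frame", "whisker_id", theta_fit = "theta",
                  phi_fit = "phi", zeta_fit = "zeta")
  j <- dplyr::left_join(j, pose, by = c("frame", "whisker_id"))
  cpn <- track_columns[3:11]
  j |>
    dplyr::group_split(.data$whisker_id) |>
    purrr::map_dfr(function(g) {
      ok <- g$status %in% c("tracked", "curated")
      d2 <- numeric(nrow(g))
      for (cc in cpn) d2 <- d2 + (g[[cc]] - g[[paste0(cc, ".true")]])^2
      tibble::tibble(
        whisker_id = g$whisker_id[1],
        n_frames = nrow(g),
        lock_rate = mean(ok),
        cp_rmse = sqrt(mean(d2[ok] / length(cpn))),
        theta_rms = angle_rms(g$theta_fit, g$theta),
        phi_rms = angle_rms(g$phi_fit, g$phi),
        zeta_rms = angle_rms(g$zeta_fit, g$zeta))
    })
}

angle_rms <- function(fit, true) {
  d <- fit - true
  d <- (d + 180) %% 360 - 180
  sqrt(mean(d^2, na.rm = TRUE))
}
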