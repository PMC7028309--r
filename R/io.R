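#' Read a grayscale image sequence from a directory
#'
#' Frames are 8- or 16-bit grayscale TIFF or PNG files whose lexicographic
#' filename order is the temporal order. Intensities are returned in
#' `[0, 1]` (16-bit frames are scaled by their full range, so an 8-bit
#' quantisation of the same data differs by at most 1/255).
#'
#' @param directory Directory containing the frames.
#' @param pattern Filename regular expression (default TIFF/PNG).
#' @return List of image matrices with attributes `files`, `shape`.
#' @export
read_image_sequence <- function(directory,
                                pattern = "\\.(tif|tiff|png)$") {
  files <- sort(list.files(directory, pattern = pattern,
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no frames found in ", directory)
  imgs <- purrr::map(files, read_gray)
  shapes <- unique(purrr::map(imgs, dim))
  if (length(shapes) != 1)
    stop("mixed frame shapes in ", directory)
  structure(imgs, files = basename(files), shape = shapes[[1]])
}

read_gray <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]  # drop colour channels
  img
}

#' Pair horizontal and vertical image sequences into frames
#'
#' @param seq_h,seq_v Image lists from [read_image_sequence()].
#' @return List of frame pairs (`frame`, `h`, `v`).
#' @export
pair_sequences <- function(seq_h, seq_v) {
  if (length(seq_h) != length(seq_v))
    stop("horizontal and vertical sequences have different frame counts (",
         length(seq_h), " vs ", length(seq_v), ")")
  purrr::map(seq_along(seq_h), function(i)
    list(frame = i, h = seq_h[[i]], v = seq_v[[i]]))
}

#' Write a synthetic scene to image files
#'
#' Writes the two views of every frame as zero-padded 8-bit TIFFs under
#' `horizontal/` and `vertical/`, and the ground truth as CSV.
#'
#' @param scene A `whisker_scene`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dh <- file.path(dir, "horizontal"); dv <- file.path(dir, "vertical")
  dir.create(dh, recursive = TRUE, showWarnings = FALSE)
  dir.create(dv, recursive = TRUE, showWarnings = FALSE)
  for (fp in scene$frames) {
    name <- sprintf("frame_%06d.tif", fp$frame)
    tiff::writeTIFF(fp$h, file.path(dh, name), bits.per.sample = 8L)
    tiff::writeTIFF(fp$v, file.path(dv, name), bits.per.sample = 8L)
  }
  readr::write_csv(scene$truth, file.path(dir, "truth.csv"))
  write_calibration(scene$model, file.path(dir, "calibration.json"))
  invisible(dir)
}

#' Read / write the run configuration
#'
#' Plain-text YAML holding scene, motion, tracker and weight settings.
#' Unknown top-level keys are rejected so typos do not silently fall back
#' to defaults.
#'
#' @param path YAML file path.
#' @return A named list of configuration sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("scene", "motions", "tracker", "weights", "pixel_mm", "seed",
             "n_frames", "disk")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg
}

# Build package objects from a parsed config list (missing sections fall
# back to package defaults).
config_objects <- function(cfg) {
  scene <- do.call(scene_config, cfg$scene %||% list())
  weights <- do.call(regularizer_weights, cfg$weights %||% list())
  tracker_args <- cfg$tracker %||% list()
  tracker_args$weights <- weights
  config <- do.call(tracker_config, tracker_args)
  motions <- if (!is.null(cfg$motions)) {
    purrr::map(cfg$motions, function(m) {
      m$base <- as.numeric(m$base)
      do.call(motion_model, m)
    })
  } else default_motion_set(3, scene)
  list(scene = scene, config = config, motions = motions,
       seed = cfg$seed %||% 1, n_frames = cfg$n_frames %||% 100)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
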