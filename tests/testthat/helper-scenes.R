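# Shared fixtures: a compact 240x240 stereo scene keeps unit tests fast;
# the acceptance tests use the full 480x480 defaults.

helper_camera <- function() {
  default_camera_model(image_size = c(240L, 240L), centre = c(120, 120, 120))
}

helper_scene <- function(noise_sd = 0.02, ...) {
  scene_config(image_size = c(240L, 240L), noise_sd = noise_sd,
               snout = list(enabled = TRUE, y0 = 165, bow = 15,
                            side_h = "high", v0 = 190, v_bow = 5,
                            side_v = "high", intensity = 0.12),
               ...)
}

helper_motion <- function(base = c(120, 162, 120), ...) {
  motion_model(base = base, length_mm = 3.0, ...)
}

# Lazily built, cached scene + tracks used by several test files.
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

small_tracked_fixture <- function() {
  cached("small_tracked", function() {
    scn <- generate_whisking_sequence(helper_scene(), helper_motion(), 30,
                                      helper_camera(), seed = 42)
    cfg <- tracker_config()
    tracks <- track_video(scn, init_from_truth(scn, cfg), cfg)
    list(scene = scn, tracks = tracks, config = cfg)
  })
}

random_curve <- function() {
  m <- matrix(stats::rnorm(9, sd = 20), 3, 3)
  m[3, ] <- m[3, ] + c(40, 0, 0)            # guarantee a nonzero chord
  bezier3d(m[1, ], m[2, ], m[3, ])
}

rotation_from_angles <- function(a, b, c) {
  whisker3d::compose_pose(a, b, c, degrees = FALSE)
}
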