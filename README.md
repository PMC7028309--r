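# whisker3d

Automatic 3D tracking of rodent whiskers from synchronized horizontal +
vertical ("stereo") high-speed video.

Rodents sweep their whiskers through 3D: each whisker changes azimuth
(θ), elevation (φ) and rolls about its own axis (ζ), and during object
contact it bends. Single-camera imaging in the horizontal plane measures
only one of the three angles, and the apparent (projected) curvature it
reports is contaminated by roll — a whisker that merely rolls looks like
it is bending. whisker3d implements the full 3D alternative for
head-fixed preparations with telecentric optics:

* **Calibration.** Both views are orthographic projections,
  `pH = H p + h`, `pV = V p + v`, with `H` fixed by construction; the
  vertical mapping `(V, v)` is fitted by linear regression from a pin
  sequence (`fit_vertical_mapping()`).
* **Tracking.** The basal segment of each whisker is a quadratic 3D
  Bezier curve `b(s) = cp0 (1-s)^2 + 2 cp1 (1-s)s + cp2 s^2` fitted per
  frame by minimising
  `E = Eh + Ev + R1 + R2` — the image line integrals of the two
  projections plus a temporal-contiguity prior (distance from the
  linearly extrapolated control points) and a shape prior (middle control
  point pinned over the chord midpoint). Only 7 scalars are free per
  whisker per frame: endpoint motion along the shaft is excluded by
  restricting `cp0`/`cp2` to the planes normal to the endpoint tangents.
  Accepted fits are renormalized to reference arc length and
  snout-distance so the tracked segment never drifts along the shaft
  (`track_video()`).
* **Kinematics and shape.** Per frame: (θ, φ, ζ) from a closed-form
  Euler decomposition of the whisker-centric frame; 3D curvature
  `kappa3d = |b' x b''| / |b'|^3` at the base (rigid-motion invariant,
  1/mm); planar curvatures for comparison; and the bending-moment proxy
  `dkappa3d = kappa3d - kappa3d_0` relative to contact-free resting
  frames (`whisker_kinematics()`).
* **Synthetic benchmark.** A seeded generator renders whisking whiskers,
  snout, pole, slip events, contact-like curvature ramps, and the rigid
  rotating circular-edge control, with exact ground truth
  (`generate_whisking_sequence()`, `generate_disk_sequence()`), so every
  stage is testable offline without recorded video.

## Worked example

A compact end-to-end run on a synthetic 240x240 scene (one whisker,
60 frames of free whisking):

```r
library(whisker3d)

model <- default_camera_model(image_size = c(240L, 240L),
                              centre = c(120, 120, 120))
scene <- scene_config(image_size = c(240L, 240L),
                      snout = list(enabled = TRUE, y0 = 165, bow = 15,
                                   side_h = "high", v0 = 190, v_bow = 5,
                                   side_v = "high", intensity = 0.12))
motion <- motion_model(base = c(120, 162, 120), length_mm = 3.0)
scn <- generate_whisking_sequence(scene, motion, n_frames = 60,
                                  model = model, seed = 1)

cfg <- tracker_config()
tracks <- track_video(scn, init_from_truth(scn, cfg), cfg)
glance(tracks)
#> # A tibble: 1 × 5
#>   whisker_id n_frames lock_rate mean_E n_lost
#>   <chr>         <int>     <dbl>  <dbl>  <int>
#> 1 w1               60         1  0.232      0

eval_tracks(tracks, scn$truth)
#> # A tibble: 1 × 7
#>   whisker_id n_frames lock_rate cp_rmse theta_rms phi_rms zeta_rms
#>   <chr>         <int>     <dbl>   <dbl>     <dbl>   <dbl>    <dbl>
#> 1 w1               60         1   0.192     0.300    1.21     3.73

kin <- whisker_kinematics(tracks, scene$pixel_mm, resting_frames = 1:20)
dplyr::select(tibble::as_tibble(kin[30, ]),
              frame, theta, phi, zeta, kappa3d, dkappa3d)
#> # A tibble: 1 × 6
#>   frame theta   phi  zeta kappa3d dkappa3d
#>   <int> <dbl> <dbl> <dbl>   <dbl>    <dbl>
#> 1    30 -80.5 -1.54 -24.2   0.153  0.00250
```

Reading the output: the whisker stayed in lock on all 60 frames
(`lock_rate` 1) with control points within ~0.2 px of ground truth;
recovered azimuth tracks the generator to 0.3° RMS. Elevation and
especially roll are the weakly observable directions — roll enters the
image only through the out-of-plane bow of the segment, so this short
3 mm demo whisker recovers it to ~4° RMS (the full-scale 4.2 mm
benchmark whiskers reach ~1°; see the methods vignette). `kappa3d` sits
at the whisker's intrinsic 0.15 mm⁻¹ and the bending-moment proxy
`dkappa3d` hovers near zero because there is no contact in this scene.

Plotting helpers: `autoplot(kin)` (angle/curvature time series) and
`autoplot(tracks, model = model)` (projected curves in both views).
Command-line use (`simulate`, `calibrate`, `track`, `kinematics`,
`eval`) goes through `cli_main()` or the thin wrapper in
`inst/cli/w3d.R`.

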