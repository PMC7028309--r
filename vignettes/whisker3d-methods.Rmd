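---
title: "Tracking whiskers in 3D: model, priors and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking whiskers in 3D: model, priors and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

whisker3d reconstructs the 3D state of rodent whiskers from synchronized
horizontal and vertical high-speed views. This vignette explains the model
behind the tracker, the priors and parameters that matter, how the
synthetic benchmark is constructed, and the numerical and design choices a
user should know about before trusting the output.

## Imaging model

Both cameras image through telecentric lenses, so each view is an
orthographic (affine) projection of the head-centred frame (x
anterior-posterior, positive posterior; y medio-lateral, positive medial;
z dorso-ventral, positive dorsal; units of horizontal-camera pixels,
0.047 mm/px by default):

$$p^H = H\,p^{3D} + h, \qquad p^V = V\,p^{3D} + v.$$

The horizontal camera shares axes and origin with the 3D frame, so
$H = [1\,0\,0;\,0\,1\,0]$ and $h = 0$ by construction; only the eight
entries of the vertical mapping $(V, v)$ are free. They are estimated by
ordinary least squares from a pin sequence spanning the imaged volume
(`fit_vertical_mapping()`), and the fit quality is summarised as residual
variance in percent of the total $(v, w)$ variance — well below 0.1% for a
working rig and for the synthetic pin sequences. Because the projections
are affine, the locus in the vertical view consistent with a horizontal
click is a straight epipolar line, which is what makes three clicks per
view sufficient to initialise a 3D curve.

## Whisker model and cost function

The basal segment of each whisker is a quadratic 3D Bezier curve

$$b(s) = cp_0 (1-s)^2 + 2\,cp_1 (1-s)s + cp_2\,s^2, \qquad 0 \le s \le 1,$$

the lowest-degree curve that describes basal whisker shape well while
keeping the parameter count at nine. Per frame and per whisker the tracker
minimises

$$E = E_h + E_v + R_1 + R_2,$$

where $E_h, E_v$ are line integrals of image intensity along the curve's
two projections (trapezoidal rule over 64 uniform parameter samples,
bilinear interpolation between pixels — dark whiskers on a bright backlit
field make low values mean good alignment), $R_1$ penalises departure from
the control points linearly extrapolated from the two previous frames
(temporal contiguity), and $R_2$ penalises the along-chord component of
the middle control point drifting away from the chord midpoint (shape
complexity; see below). Integration is over the curve parameter rather
than arc length, which makes the constant-image case exact and matches the
line-integral definition; an arc-length-weighted variant is available via
`line_integral_cost(weight = "arclength")`.

Only seven scalars are free in the per-frame minimisation: all three
components of $cp_1$, plus the two components of each endpoint in the
plane normal to the curve tangent at that end (tangent directions frozen
at the seed). Sliding of the endpoints along the whisker shaft is thereby
excluded from the search space — that direction is almost invisible to the
image term and would otherwise accumulate as drift. Minimisation is BFGS
with forward-difference gradients (step $10^{-3}$ px), capped at 200
iterations with relative tolerance $10^{-6}$; the fit never reports a
higher cost than its seed.

After a fit is accepted, the curve is *renormalized*: the fitted parabola
is kept fixed and only its parameter interval is moved (an exact
sub-segment, `bezier_reparam()`) so that (a) the arc distance from the
snout-contour intersection of the proximally extrapolated curve to $cp_0$
and (b) the segment arc length both equal reference values stored at
initialisation. Both constraints are solved by root finding on the
monotone arc-length function and are exact to the stated tolerances; shape
is untouched because the parabola is the same point set.

### The shape prior selects a parameterization, not a shape

Control points of a quadratic arc are not unique: sliding $cp_1$ along the
chord direction (with compensating endpoint changes) reparameterises
nearly the same point set. $R_2$ exists because for near-straight whiskers
this degeneracy lets the middle control point migrate and produce wild
extrapolations. Its minimiser — middle control point above the chord
midpoint — is exactly the *vertex-symmetric* parameterization of a
parabolic segment. The synthetic generator therefore writes its ground
truth in that canonical parameterization, which makes truth-to-fit
control-point comparisons well-posed. A corollary worth knowing: the
endpoint curvature of a symmetric quadratic segment of half-chord $a$
cannot exceed $\approx 0.385/a$, so strongly bent states require a shorter
segment (the generator raises an explicit error rather than silently
rendering an unrepresentable shape).

### Default gains

Both regularizer gains are in px² and larger values mean weaker priors.
`sigma1 = 50` keeps $R_1$ at the few-percent level of $E$ for smooth
whisking sampled at 1000 frames/s while making slip-like discontinuities
expensive enough to break lock (which is the desired behaviour — slips
should be flagged, not chased). `sigma2 = 50` pins the image-degenerate
along-chord coordinate without influencing observable shape.

## Tracking loop, lock threshold, re-acquisition

Initialisation is either manual-equivalent (three $(x, y)$ positions plus
their epipolar matches; `manual_initialize()`), template-based from a
previously tracked video (`auto_initialize()`; each template is ranked by
its best cost over integer translations within ±5 px in x and z, because a
template a few pixels off an 1 px-wide ridge already images as pure
background), or scripted from synthetic ground truth
(`init_from_truth()`).

Each whisker then proceeds independently frame by frame: snout contour
detection, control-point extrapolation, fit, renormalization. A fit is
accepted while $E$ stays below the whisker's lock threshold, whose default
is estimated from the initialisation frame as twice the mean plus five
robust SDs of the pooled on-curve intensity samples — an estimate of the
worst image cost a correctly locked curve should produce. Above threshold
the frame is flagged `lost` and, for up to 50 subsequent frames, the
tracker attempts re-acquisition by the same ±5 px translation search
around the last accepted solution; with oscillatory whisking the whisker
re-enters the capture range within a fraction of a whisk cycle. Beyond the
window the whisker stays lost until curated (`curate()` + `retrack()`).

Snout contours are detected per frame per view: 5×5 median filtering
removes fur and whisker fine structure, Gaussian smoothing (SD 12 px)
leaves a single strong edge, and the contour is placed at the
bright-to-dark extremum of the directional gradient (per column in the
horizontal view, per row in the vertical view) with 3-point parabolic
sub-pixel refinement. Positions whose extremum falls below five times the
robust noise level of the gradient field are masked; the noise level is
estimated from second differences of the gradient along the search axis,
which removes the (heavily smoothed, hence locally linear) edge response.

## 3D kinematics and shape

At every tracked frame the whisker-centred frame is $i'$ = unit tangent at
$s = 0$, $j'$ = unit second derivative re-orthogonalised against $i'$ (for
a general quadratic $b''$ need not be perpendicular to the base tangent),
$k' = i' \times j'$. Azimuth, elevation and roll are the intrinsic
z–y–x Euler angles of that frame,
$R = R_z(\theta)R_y(-\varphi)R_x(\zeta)$, extracted in closed form;
the decomposition provably minimises the matrix alignment residual (the
test suite checks it against brute-force minimisation). Azimuth agrees
with the classical planar definition away from gimbal lock; elevation is
positive when the tip points dorsally; roll is zero when the bending-plane
normal aligns with head z after removing azimuth and elevation, so a
whisker curving straight downward has roll near −90°. The Euler order is a
modelling choice (the angles are standard but their order is not dictated
by their definitions); it is fixed, documented, and verified against the
direct minimisation.

Shape is summarised by the space-curve curvature
$\kappa_{3D} = |b' \times b''| / |b'|^3$ at $s = 0$ (reciprocal
osculating-circle radius, reported in 1/mm), which is invariant to rigid
motion, unlike the planar projections $\kappa_h$ (from the $x, y$
components) and $\kappa_v$ (from the head-frame $z, y$ components; an
image-frame $(v, w)$ variant is available via
`curvature_planar(image_frame = TRUE)`). For a quadratic the torsion is
identically zero, so the only nonzero bending-moment component is the one
normal to the bending plane, and under quasi-static contact it is
proportional to $\Delta\kappa_{3D} = \kappa_{3D} - \kappa_{3D,0}$, the
departure from the resting curvature (mean over user-specified
contact-free frames). `whisker_kinematics()` assembles all of these into
one tidy table.

## The synthetic benchmark

The generator exists so the entire pipeline can be validated offline with
exact ground truth. It emulates: backlit dark whiskers with a Gaussian
cross-section (SD 1 px, matching the 2–3 px image width of a mouse whisker
base), a dark smooth-contoured snout region, optional pole occluder,
additive Gaussian pixel noise (SD 0.02 of full scale — backlit imaging is
high-SNR), 480×480 px views at 1000 frames/s, and whiskers as rigid planar
parabolas (intrinsic curvature 0.15 mm⁻¹, comparable to the rigid test
object used for curvature validation; segment length 4.2 mm) rotated about
fixed base points. Azimuth is sinusoidal (default 20° amplitude at 10 Hz,
giving a mean angular speed near the free-whisking speeds observed in
task-performing mice); elevation and roll are linearly coupled to azimuth
(anti-correlated elevation, whisker-dependent roll slope), matching the
strong coupling seen in vivo. Slip events add an instantaneous azimuth
offset; contact episodes add a per-frame curvature ramp. Bases sit ~3 px
lateral of the snout contour with near-normal incidence, so the
snout-distance reference used by renormalization is nearly
pose-independent, as it is for a real follicle that moves with the skin.

What the generator does *not* emulate: fur texture, motion blur,
perspective, non-rigid shape change along the shaft (other than the
scripted curvature ramp), whisker taper, and occlusion by body parts.
Passing the synthetic benchmarks therefore demonstrates correctness of
the geometry, cost, optimisation and bookkeeping — not robustness to every
nuisance in real video, which is what the curation tools are for.

The rigid rotating-edge control re-creates the physical validation
experiment: a 13 mm-diameter circular edge (glass coverslip on a
medio-lateral rod) rolled about the rod axis while oscillating in azimuth,
so the projected planar curvatures swing strongly while true 3D shape
never changes. The rendered phantom is the rigid *quadratic* segment whose
$\kappa_{3D}$ at the tracked base point is exactly 2/diameter, rather than
a resampled circle: any quadratic confined to a circular arc of half-angle
$\alpha$ has endpoint curvature biased by a factor $\cos^2\alpha$ (8–10%
for a realistic segment length), a curve-family approximation bias that
would confound the rigidity property under test with model capacity.
`generate_disk_sequence(edge = "circle")` renders the true arc for anyone
who wants to study that bias itself.

## Numerical choices

* Image coordinates are 0-based with pixel centres at integer positions;
  x indexes columns and y rows of the horizontal image.
* Arc lengths use adaptive quadrature (rel. tol. 1e-8) in the public API
  and a fixed 24-node Gauss–Legendre rule inside renormalization's root
  finding, where the integrand (speed of a quadratic) is smooth and the
  adaptive machinery would dominate runtime.
* Rendering computes, for every pixel near a curve, the squared distance
  to a dense polyline (≤0.3 px spacing) and applies the Gaussian profile;
  ridge fields are exact to well under 1% of contrast.
* Out-of-frame excursions during optimisation are handled smoothly
  (clamped border sampling plus a penalty proportional to the mean
  excursion); the public cost function errors once more than 25% of
  samples leave the frame.
* Degenerate cases error explicitly: zero chords, straight curves in
  roll extraction, rank-deficient calibration geometry, missing snout
  intersections (renormalization is then skipped and flagged).

## Known limitations

* **Roll (and to a lesser degree elevation) is weakly observable per
  frame.** Roll enters the image only through the out-of-plane component
  of the segment's bow (a few pixels for realistic curvature); sub-0.1 px
  localisation differences move the fitted roll by a degree with almost no
  cost change. On the synthetic benchmark azimuth is recovered to ~0.2°
  RMS and control points to ~0.2 px, while elevation settles around
  0.5–0.7° and roll around 1° RMS — a property of the information content
  of this imaging geometry, not of the optimiser (deeper optimisation and
  pose smoothing were both verified not to change it materially). Treat
  frame-by-frame roll as a band-limited estimate.
* Whisker identity is positional: curves that swap targets during heavy
  overlap are not re-identified automatically; the cost threshold flags
  most such events for curation.
* The quadratic family bounds how much bending a segment of given length
  can represent (see above); strongly bent contact episodes need shorter
  segments.
* Benchmark problem sizes used by the automated validation (100-pin
  calibration, 200-frame rigid-edge control, 300-frame 8-whisker
  benchmark, 150-frame recovery sequences) were chosen to exercise every
  code path at full image resolution while keeping a complete validation
  run in the minutes range on one core.
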