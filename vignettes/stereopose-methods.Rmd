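---
title: "Stereo posture reconstruction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereo posture reconstruction: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stereopose` reconstructs the 3D posture of a seated subject from two
synchronized cameras and the per-frame output of a 2D pose detector in the
BODY_25 convention. This vignette is the package's own account of the
underlying models, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the places where the design was
genuinely open.

## 1. The measurement model

### Camera model

Each camera is a pinhole with radial–tangential distortion. A world point
$X$ (mm) maps to pixels via

$$x_c = R\,X + t,\qquad
  x_n = (x_c^{(1)}/x_c^{(3)},\; x_c^{(2)}/x_c^{(3)}),$$

then the Brown–Conrady polynomial with radial terms $k_1, k_2, k_3$ on the
normalized radius and tangential terms $p_1, p_2$, and finally the
intrinsics $(f_x, f_y, c_x, c_y, s)$. Pixel coordinates are continuous
(detector output is sub-pixel), origin top-left, x rightward, y downward,
no half-pixel offset. Assumptions: fixed focus and fixed intrinsics over a
session (the target hardware has no autofocus), global shutter, one rigid
pose per camera. Undistortion inverts the polynomial by fixed-point
iteration (at most 50 sweeps, tolerance $10^{-12}$ in normalized units);
over the normalized radii a 60°-field-of-view camera produces, the map is
contractive for mild distortion and the iteration converges in a handful of
sweeps.

The distortion parameterization is a design choice: the calibration
literature around planar targets almost universally uses the
radial–tangential model, so the package adopts it (three radial + two
tangential terms, with only $k_1, k_2$ estimated by default) without
claiming fidelity to any specific toolbox.

### World frame

The world frame **is** the camera-1 frame: camera 1 has the identity pose
and the only extrinsic unknown is the camera-2-from-camera-1 relative pose.
This matches the stereo-calibration convention and removes an
unidentifiable global gauge. Consequently the world axes are arbitrary up
to how camera 1 was mounted; `axis_angle_series()` and the pipeline config
accept an optional world-alignment rotation for users who want, say, the
vertical exactly along y. The synthetic rig is built so that camera 1's y
axis (pointing down, image-like) is the vertical of the scene, which makes
a straight back have a neck-to-mid-hip angle of about 0° to the y axis
with no alignment transform.

## 2. Planar stereo calibration

Corner *detection* is out of scope — the package consumes corner
coordinates (CSV per camera: `view_id, corner_index, x_px, y_px`), because
the contribution chain here is geometric, not photometric. The default
board is 8 × 15 squares of 51 mm (so 765 mm × 408 mm, a 7 × 14 = 98
inner-corner grid). Reading "rows and columns" as *squares* is confirmed
by the board's printed dimensions: 8 · 51 = 408 and 15 · 51 = 765.

The closed-form stage is the standard planar-calibration chain:

1. **Homography per view** by normalized DLT (Hartley normalization of
   both point sets, SVD null vector, $h_{33} = 1$ gauge). Degenerate
   (collinear, < 4 point) configurations are rejected by the ratio of the
   8th to 1st singular value.
2. **Intrinsics** from the image-of-the-absolute-conic constraints: each
   view contributes two linear equations in the 6-vector parameterizing
   $\omega = K^{-\mathsf{T}}K^{-1}$; the stacked system is solved by SVD
   and $K$ extracted by the usual back-substitution. At least three views
   in general position are required; a vanishing *second-smallest*
   singular value signals a degenerate view set (the smallest one is the
   solution itself and is legitimately near zero on clean data).
3. **Per-view board poses** from $K^{-1}H$, scale fixed by the first
   column's norm, rotation completed by cross product and re-orthonormalized
   by SVD (nearest rotation), sign fixed by the board-in-front constraint.
4. **Relative pose** per view as $R_2R_1^{\mathsf{T}}$,
   $t_2 - R_2R_1^{\mathsf{T}} t_1$, aggregated over views by quaternion
   averaging (dominant eigenvector of the summed quaternion outer
   products — sign-invariant) and arithmetic-mean translation.

Distortion is frozen at zero through the closed-form stage — estimating it
there destabilizes the linear solves — and enters only in the nonlinear
refinement: a Levenberg–Marquardt minimization (`minpack.lm::nls.lm`,
numeric Jacobian, up to 100 iterations) of the total squared reprojection
error over both cameras' $(f_x, f_y, c_x, c_y, k_1, k_2)$, all per-view
board poses (Rodrigues parameterization), and the relative pose. Skew is
held at zero in refinement; modern sensors justify it. If the optimizer
fails to improve, the initialization is returned with a
`refinement-diverged` status rather than a worse fit.

The audit statistic is the mean reprojection error: per corner the pixel
distance between observation and projection, per view the mean over
corners and both cameras, overall the corner-count-weighted mean of the
per-view values. This mirrors the bar-chart-per-view audit used with
stereo calibration tools; the weighted-mean identity is asserted in the
tests. On synthetic corners with isotropic Gaussian noise $\sigma$, the
expected per-corner error at the true parameters is the Rayleigh mean
$\sigma\sqrt{\pi/2}$, which the test suite uses as an independent oracle.

## 3. Triangulation

Each jointly visible keypoint is triangulated by the linear DLT on
*normalized* coordinates (undistort first, then $P_1 = [I\,|\,0]$,
$P_2 = [R\,|\,t]$, SVD of the stacked 4 × 4 system). Design choice: no
per-point nonlinear polish. The reference workflow this package models
uses a single library triangulation call per point; instead of polishing,
the per-camera reprojection errors of every triangulated point are
returned so residuals are visible rather than hidden. The test suite
cross-checks the DLT against an independent midpoint-method oracle (closest
point between the back-projected rays) — two genuinely different
formulations that must agree to $10^{-6}$ mm on noiseless data.

Degeneracy policy: exactly coincident camera centers are a hard error;
ray angles below 0.1° produce a warning but still return the point, since
near-parallel rays give a usable direction even when depth is poorly
conditioned.

Confidence gating: a keypoint enters triangulation only if its detector
confidence reaches `c_min` in **both** cameras on that frame (simultaneity
is what makes a stereo correspondence). The default `c_min = 0.1` is
deliberately permissive: the rig geometry this package targets was chosen
by its users precisely so that all 25 keypoints are visible in both views,
so gating mainly removes outright detector failures (confidence 0,
coordinates (0, 0)). Invalid keypoints propagate as missing values — never
as zeros — through every downstream statistic.

Synchronization is an integer frame shift supplied by the user (the
reference workflow aligned its two videos in post-processing; no automatic
temporal alignment is attempted, and sub-frame interpolation is a
non-goal).

## 4. Ergonomic metrics

Thirteen segments are cataloged: the eye pair, two neck–shoulder links,
upper/lower arms, the head axis (neck→nose), the back (neck→mid-hip), and
upper/lower legs. Segment vectors run proximal→distal; with angles
measured in [0°, 180°] the orientation choice is sign-safe. Per frame,

* length $\ell_t = \lVert d_t - p_t\rVert$ (mm), missing if either
  endpoint is missing;
* axis angle $\theta_{a,t} = \arccos\bigl((d_t - p_t)\cdot\hat e_a /
  \lVert d_t - p_t\rVert\bigr)$ (deg), so the direction-cosine identity
  $\cos^2\theta_x + \cos^2\theta_y + \cos^2\theta_z = 1$ holds exactly;
  for a segment lying in the y–z plane with both direction cosines
  non-negative, $\theta_y + \theta_z = 90°$.

Summaries use the arithmetic mean and the sample standard deviation
(n − 1; defined as 0 for a single value). Box-plot statistics use
inclusive linear interpolation of order statistics (`quantile type 7`), so
plots are reproducible from the five numbers. Percentage differences are
**right-to-left over the right-side mean** and **reconstructed-to-real
over the reconstructed mean**, rounded half-away-from-zero to one decimal.
Neither denominator convention is universal; these were chosen because
they exactly reproduce the published worked-example cells that are
internally consistent (the test suite pins all of them), and they are
applied uniformly. A handful of published cells are not reproducible under
*any* single rounding rule (e.g. a row printing identical real and
reconstructed lengths alongside a non-zero difference); those are treated
as typographical and excluded rather than guessed at.

Posture keyframes (straight / on the tank / left turn / right turn, with
their occurrence times) are attached to any series by nearest-frame
rounding; at 30 fps a 6.5 s keyframe lands on frame 195, and marker times
are always within half a frame period of the requested time.

## 5. The synthetic scene generator

The generator exists because the package's central validity argument —
*rigid segments must come back rigid* — needs data with known ground
truth.

**Mannequin.** A 25-keypoint kinematic tree rooted at the mid-hip, with
every tree edge a rigid length. Defaults (mm): upper arm 255, lower arm
250, upper leg 342, lower leg 380, inter-eye distance 58, neck–shoulder
160, back 520, head 190; the remaining links (ears, feet, hip offsets) are
plausible adult constants. The eye pair is chained nose→right-eye→left-eye
so the inter-eye distance is itself a tree edge and therefore exactly
rigid. The mannequin is bilaterally symmetric by default, which is what
makes the left/right asymmetry statistic a pure noise measure.

**Motion.** Four posture keyframes on the reference schedule (1.5 s, 6.5 s,
14.5 s, 21.4 s over a 25 s clip at 30 fps) are built by rotating the
torso/head/arm edge directions of a neutral seated pose: 42° forward pitch
for "on the tank", 35° pitch with ±20° roll for the turns, legs fixed
(feet on the pegs). Between keyframes each keypoint is linearly
interpolated and the pose is then re-projected onto the rigid-limb
constraint (each child re-placed along the interpolated bone direction at
the exact edge length), so every frame honors the lengths to $10^{-9}$ mm.
The torso stays in the y–z plane between the straight and tank postures,
which is what the angle-complementarity check exploits.

**Rig.** Two identical cameras: HD 720p (1280 × 720) with the focal length
implied by a 60° horizontal field of view ($f \approx 1108.5$ px),
converging geometry with a relative rotation of 25° yaw (top view)
composed with 30° pitch (side view) — yaw first, both about camera-1 axes;
the published geometry names the two plane angles but not their
composition order, so both are explicit configuration with these defaults.
The baseline (default 2000 mm, a realistic lab scale; the reference setup
does not publish one) fixes the scale: camera 2 is placed so both optical
axes intersect at $d = b / (2\sin(\theta_z/2))$ where $\theta_z$ is the
angle between the axes, putting the working volume near 3 m. Default
distortion is zero (an ideal pinhole): the fixed-FoV webcams modelled here
are mild, no magnitude is published, and a zero default keeps the
generator's ground truth inside the $k_1,k_2$ refinement model; distortion
is fully supported and exercised with non-zero coefficients in the unit
tests.

**Noise.** Isotropic Gaussian pixel noise (default $\sigma = 1$ px — chosen
once as a realistic detector jitter magnitude; no quantitative detector
noise is published, only that reconstructed lengths fluctuate around their
means), independent per-keypoint per-camera dropout (default 0.02), and
confidences drawn from Beta(8, 2) (mean 0.8) for visible keypoints, 0 for
dropped ones — arbitrary but documented and overridable. With noise and
dropout both zero, confidences are pinned at the Beta mean so the dataset
is fully deterministic. Identical seeds give byte-identical datasets.

**What the generator does not emulate.** Image content: shadows, lighting
changes, occlusion by the motorcycle, and the detector's systematic
keypoint re-definitions as the subject rotates. Its noise is white and
isotropic, whereas real detector error is temporally correlated and
anisotropic. A passing noiseless round trip therefore demonstrates the
*geometry* is implemented correctly; a passing noisy run demonstrates
statistical stability under idealized noise — neither is evidence about
detector behavior on real footage.

## 6. Numerical choices and degenerate inputs

* Rotations are validated to orthonormality and unit determinant at
  $10^{-10}$ and re-orthonormalized (SVD) after composition chains.
* Homography/conic/triangulation solves all go through SVD; rank checks
  use singular-value ratios ($10^{-12}$ for homographies, $10^{-10}$ for
  the conic system).
* The refinement accepts only non-increasing total squared error;
  divergence returns the initialization with a warning status.
* Serialization (YAML calibration and config files) writes 15 significant
  digits so poses survive a round trip within validation tolerance.
* Empty inputs (no valid frames for a segment, empty directories, empty
  value vectors) are hard errors, not NAs, so silent all-missing analyses
  cannot happen.

## 7. Problem sizes used in the checks

The packaged validation runs at the study's own scale: 25 s clips at
30 fps (750 frames, 25 keypoints), 15 calibration views of the 98-corner
board, 200 random configurations for the triangulation cross-check, 0.5 px
corner noise and 1 px keypoint noise for the stochastic checks. Unit tests
use shorter clips (0.2–10 s) of the same generator.

## 8. Known limitations

* Two cameras only; no multi-view (> 2) fusion or bundle adjustment over
  scene points.
* No temporal smoothing or outlier rejection beyond confidence gating —
  deliberately, so the audit statistics measure the raw reconstruction.
* Single subject per scene (the detector's first person is taken, with a
  warning).
* Segment-to-axis angles only; inter-segment (flexion) angles and
  RULA/REBA-style scoring are out of scope.
* The world frame is camera-1-relative; absolute vertical requires either
  careful mounting or the world-alignment rotation.
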