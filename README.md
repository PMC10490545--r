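# stereopose

Marker-less 3D reconstruction of human posture from two ordinary cameras.

`stereopose` is aimed at ergonomics studies of seated subjects — the
motivating application is a motorcyclist on a road bike — where a
marker-based motion-capture system is impractical and the standard
work-around, 2D joint angles from a single lateral view, throws away the
out-of-plane information. The package takes the per-frame output of a 2D
pose detector (the BODY_25 convention: 25 keypoints, each an `(x, y,
confidence)` triple per camera per frame), calibrates the two-camera rig
from checkerboard views, triangulates every jointly visible keypoint into
metric 3D, and derives the ergonomic quantities of interest: body
segment-length time series (the stability check that the reconstruction is
trustworthy — bones do not stretch) and segment-to-axis angle time series
(the posture measure itself).

## Method

**Planar calibration.** Each camera is modelled as a pinhole with
radial–tangential lens distortion. For every checkerboard placement the
board-to-image homography H is estimated by normalized DLT; each H yields
two linear constraints on the image of the absolute conic
ω = K⁻ᵀK⁻¹, from which the intrinsic matrix K is recovered in closed form
(≥ 3 views). Per-view board poses follow from K⁻¹H, and the camera-2-from-
camera-1 relative pose (R, t) is aggregated over views by quaternion
averaging. A final Levenberg–Marquardt refinement minimizes the total
squared reprojection error over intrinsics, distortion, board poses and the
relative pose; the per-view mean reprojection error is the audit statistic.

**Triangulation.** With the world frame fixed to camera 1, the normalized
projection matrices are P₁ = [I | 0] and P₂ = [R | t]. Observations are
undistorted to normalized coordinates and each keypoint is triangulated by
the linear DLT (SVD of the stacked 4×4 system), with per-camera
reprojection errors reported per point. A keypoint enters triangulation
only when its detector confidence reaches the threshold in **both** cameras
on that frame; everything else propagates as a missing value.

**Metrics.** For a segment with endpoints p (proximal) and d (distal),
the per-frame length is ‖d − p‖ and the axis angles are
θₐ = arccos((d − p)·êₐ / ‖d − p‖) ∈ [0°, 180°] for a ∈ {x, y, z}, so
cos²θx + cos²θy + cos²θz = 1 holds frame-wise. Summary tables report the
mean, sample standard deviation, and signed percentage differences
(right-to-left over the right mean; reconstructed-to-real over the
reconstructed mean), rounded half-away-from-zero to one decimal.

**Synthetic scenes.** Because a rigid-limbed subject is the package's
validity argument, `stereopose` ships a generator with known ground truth:
an articulated 25-keypoint mannequin that moves through the four canonical
riding postures (straight, on the tank, left turn, right turn), a virtual
converging two-camera rig (default: 25° top-view yaw plus 30° side-view
pitch between the optical axes), checkerboard calibration views, and a
detector noise model (Gaussian pixel noise, dropout, Beta-distributed
confidences) — all seeded and reproducible.

## Worked example

Simulate a 25 s ride (750 frames at 30 fps), calibrate from 15 noisy board
views, reconstruct, and summarize:

```r
library(stereopose)

rig    <- virtual_rig()                      # 25 deg yaw + 30 deg pitch, 2 m baseline
spec   <- mannequin_spec()                   # rigid limbs: upper arm 255 mm, ...
traj   <- build_motion(default_rider_keyframes(spec), spec, duration = 25)

boards <- render_checkerboard_views(checkerboard_spec(), rig,
                                    n_views = 15, noise_sd = 0.5, seed = 1)
calib  <- calibrate_stereo(boards$views)
calib
#> stereo_calibration
#>   camera 1: fx=1106.53 fy=1106.30 cx=639.18 cy=363.56
#>   camera 2: fx=1109.70 fy=1109.96 cx=642.12 cy=359.70
#>   relative rotation 38.62 deg, baseline 2000.3 mm
#>   15 views, overall mean reprojection error 0.6317 px

rend <- render_keypoint_series(traj, rig,
                               noise_model(sigma_px = 1, dropout = 0.02, seed = 1))
skel <- triangulate_series(rend$series1, rend$series2, calib)
skel
#> skeleton3d_series: 25 x 750 frames @ 30 fps, 96.1% keypoints valid

segment_length_series(skel, segment_catalog()$eyes)
#> segment 'eyes': mu = 58.4 mm, sigma = 2.6 mm (n = 691)

tab <- segment_length_table(skel)
tab[tab$segment %in% c("upper_arm_l", "upper_arm_r"), ]
#>        segment  side mu_mm sigma_mm n_valid right_left_diff_pct
#> 4  upper_arm_r right 255.1    3.005     685                 0.0
#> 5  upper_arm_l  left 255.1    2.956     690                 0.0

back_y <- annotate_schedule(axis_angle_series(skel, segment_catalog()$back, "y"),
                            default_posture_schedule(1))
round(back_y$angle_deg[back_y$markers$frame + 1], 1)
#> [1]  0.6 41.9 40.3 39.9     # straight, on the tank, left turn, right turn
```

The reading: the true 58 mm inter-eye distance comes back as 58.4 ± 2.6 mm
under 1 px detector noise, the symmetric mannequin shows 0.0 % left/right
arm asymmetry, and the back-to-vertical angle is ≈ 0° when the rider sits
straight and ≈ 40° in the bent postures — the quantities an ergonomist
actually reads off.

The same flow is available as config-driven stages
(`pipeline_simulate()`, `pipeline_calibrate()`, `pipeline_reconstruct()`,
`pipeline_metrics()`) and as a thin command-line wrapper,
`inst/scripts/stereopose-cli.R`.

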