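Package: stereopose
Title: Marker-Less Stereo Reconstruction of Human Posture from Two Cameras
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reconstructing 3D human posture from a pair of
    synchronized cameras and per-frame 2D pose-detector output in the
    BODY_25 keypoint convention.  Implements planar checkerboard stereo
    calibration (homography-based closed form with nonlinear refinement
    and a reprojection-error audit), direct-linear-transform triangulation
    of keypoints into metric 3D, and ergonomic posture metrics: body
    segment-length time series with stability statistics and
    segment-to-axis angle time series.  A synthetic-scene generator
    produces articulated rider mannequins, virtual two-camera rigs and
    checkerboard calibration datasets with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
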