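# sonotrack

Low-cost six-degree-of-freedom (6 DoF) tracking of a freehand ultrasound
probe with a single RGB camera. A regular dodecahedron carrying one square
ArUco-style fiducial marker per face is fixed to the probe body; because
the markers are distributed over a convex solid, several of them face the
camera from any viewing direction, which removes the self-occlusion
problem that plagues conventional infrared (IR) optical tracking. Tracking
the cluster pose frame-by-frame, and knowing the fixed cluster-to-image
calibration transform, every B-mode pixel can be placed in the 3D camera
frame — the geometric core of freehand 3D ultrasound.

The package provides the full desk-scale pipeline for researchers in
ultrasound-guided orthopedics and image-guided intervention:

- **SE(3) primitives** — validated rotation/translation pairs, exact
  composition/inversion, quaternion conversion with deterministic
  hemisphere normalization (`rigid_transform()`, `se3_compose()`,
  `quat_slerp()`, ...).
- **Cluster geometry** — the regular-dodecahedron marker cluster from the
  golden-ratio vertex construction, marker placement with a configurable
  edge inset, pinhole + Brown–Conrady camera model, and a self-occlusion
  visibility test (`build_dodecahedron()`, `project_points()`,
  `visible_markers()`).
- **Pose estimation** — robust Perspective-n-Point: marker-center pair
  midpoints augment the corner correspondences
  (`u_avg = (u_i + u_j) / 2` over all marker pairs), RANSAC over minimal
  PnP solutions (planar homography or DLT), then Levenberg–Marquardt
  refinement of the reprojection error over the RANSAC inliers. Both
  pose-computation routes are implemented: solving directly in the probe
  frame (`pose_direct()`) and solving the cluster pose then concatenating
  the calibration transform (`pose_concat()`).
- **Probe calibration** — the crossed-wire phantom solve
  `T_Probe = T_Cam2Dod^-1 · T_Cam2Cal`, pixel-size estimation from the
  parallel distal wires, and the in-plane image-origin offset
  (`calibrate()`).
- **Trajectory processing** — Savitzky–Golay filtering of translations,
  SLERP + linear resampling of the 200 Hz IR reference onto the 60 Hz
  camera clock, Kabsch–Umeyama rigid registration, ultrasound image-corner
  mapping (FOV 38 mm × depth 30 mm by default), and the per-axis
  mean/standard-deviation error statistics with their Euclidean norms
  (`error_stats()`).
- **Synthetic data** — a seeded simulator of smooth probe sweeps, RGB
  marker observations with pixel noise and dropout, IR reference streams
  and calibration snapshots, so the whole pipeline runs and is tested
  without hardware (`simulate()`).

## Worked example

```r
library(sonotrack)

# a 2 s simulated acquisition: 0.5 px corner noise, 10% marker dropout,
# 0.2 mm IR reference noise, camera 400 mm from the probe
cfg <- sim_config(duration = 2, pixel_noise_px = 0.5, ir_noise_mm = 0.2,
                  dropout_prob = 0.1, seed = 5)
out <- simulate(cfg)

# probe calibration from the crossed-wire snapshot
cal <- calibrate(out$snapshot)

# track, filter, align to the IR reference, evaluate
report <- run_pipeline(pipeline_config(
  out$rgb_frames, cfg$camera, cfg$model, cal, out$ir_stream,
  cfg$ir_cluster, cfg$T_world2cam, params = pose_params(seed = 5)))
print(report)
```

```
<tracking_report>
 method mean_x mean_y mean_z mean_norm std_x std_y std_z std_norm
 direct -0.025  0.010  0.119     0.122 0.259 0.124 0.527    0.600
 concat -0.017  0.007  0.096     0.097 0.329 0.159 0.636    0.734
 origin -0.030  0.016  0.109     0.114 0.093 0.086 0.397    0.417
frames: 121; failed: 1/1; ambiguous: 0/0
stage seconds: track=24.46 filter=0.02 reference=0.10 evaluate=0.04
```

Each row compares one pose-computation route against the IR reference
resampled onto the camera clock: per-axis mean error and standard
deviation of the mapped ultrasound image-corner positions (mm), with the
Euclidean norms of the two triples. `direct` solves PnP in the probe
frame; `concat` solves the cluster pose and concatenates the calibration
transform; `origin` compares cluster origins only, ignoring rotation. At
this noise level both routes agree with the reference to a few tenths of
a millimetre; errors grow with camera distance and with pixel noise.

A command-line front-end for the same pipeline is installed at
`exec/sonotrack` (subcommands `simulate`, `calibrate`, `track`,
`evaluate`).

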