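---
title: "Methods: marker-cluster probe tracking, calibration and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-cluster probe tracking, calibration and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonotrack)
```

## The measurement model

Freehand 3D ultrasound needs, for every B-mode frame, the rigid transform
that places image pixels in a fixed 3D frame. `sonotrack` estimates that
transform optically: a regular dodecahedron with one square fiducial
marker per face is attached to the probe, and a single calibrated RGB
camera observes it. Every quantity moves through a chain of SE(3)
transforms,

$$p_{cam} = T_{Cam2Dod}\; T_{Probe}\; p_{image},$$

where $T_{Cam2Dod}$ is the per-frame cluster pose, $T_{Probe}$ the fixed
cluster-to-image calibration, and $p_{image}$ a point of the ultrasound
image plane (x along the transducer array, y along the beam, z = 0; units
mm throughout). A transform is stored as a validated pair $(R, t)$ with
$R^\top R = I$, $\det R = +1$; the 4×4 homogeneous form exists only for
serialization, because the invariants live on $R$ and $t$ separately.

Two routes produce the probe pose each frame, and both are implemented
because their error behaviour differs:

* **direct** — all marker corners are first expressed in the probe frame
  (via $T_{Probe}^{-1}$) and PnP solves $T_{Cam2Probe}$ in one step;
* **concatenation** — PnP solves the cluster pose $T_{Cam2Dod}$ and the
  result is composed with $T_{Probe}$.

With noiseless input both routes coincide; under noise they weight the
reprojection residuals differently because the 3D point cloud sits in
different frames relative to the rotation center.

## Cluster geometry

The dodecahedron comes from the canonical golden-ratio vertex
construction, scaled to the requested edge length, with a deterministic
vertex and face enumeration so that two builds of the same configuration
are bit-identical. Markers are squares of 25 mm placed on each face with
their lower side parallel to the face's canonical edge at a 2.5 mm
perpendicular inset; the canonical edge is the one with the
lexicographically smallest vertex-index pair, a convention chosen because
the physical placement instruction ("parallel to an edge") does not name
the edge. Marker ids default to 0–11 in face order and are overridable.

The edge length is a free parameter (default 31 mm). The marker size and
inset constrain it from below; the constructor verifies geometrically
that every marker corner falls strictly inside its pentagon and refuses
configurations that do not fit (at 25 mm markers with 2.5 mm inset the
smallest feasible integer edge is 29 mm; 31 mm leaves a comfortable
printing margin and is the default).

Visibility uses two conditions: the face must be front-facing
($n \cdot c < 0$ with the outward normal $n$ and face center $c$ in
camera coordinates) and all four projected corners must land inside the
image. Convexity bounds the front-facing count: across 1000 random poses
with the cluster in view, between 1 and 6 of the 12 markers are visible,
which is the property the dodecahedron was chosen for.

## Robust pose estimation

Corner correspondences are augmented with one midpoint per unordered pair
of detected markers, $u_{avg} = (u_i + u_j)/2$, computed from the marker
center points (the mean of the four corners). With $k$ markers this adds
$k(k-1)/2$ points and stiffens the correspondence set when few markers
are visible. Averaging is done in image space on detected pixels, so the
package's reprojection model predicts an augmented observation the same
way — as the mean of the projected parent corners, not the projection of
the 3D midpoint. Image-space averaging and perspective projection do not
commute; modelling the point the way it was measured keeps augmented
residuals exactly zero on noiseless data, which the noiseless
round-trip tolerances (below) rely on.

Estimation then follows the classic robust scheme:

1. **RANSAC** over minimal subsets: coplanar samples (a single marker's 4
   corners) go through a plane-to-image homography decomposition,
   non-coplanar samples of 6 through DLT. Defaults: 500 iteration cap,
   2 px inlier reprojection threshold, minimum consensus 4, adaptive
   early exit at 0.99 confidence. These values are package choices (the
   underlying acquisition protocol does not state any) and are all
   overridable through `pose_params()`.
2. **Levenberg–Marquardt** refinement (via `minpack.lm`) of the
   six-parameter pose (axis-angle + translation), minimizing summed
   squared pixel reprojection error over the RANSAC inliers only, with an
   analytic Jacobian in the distortion-free case. Termination: relative
   cost change below 1e-10 or 100 iterations — tight enough that
   noiseless poses are recovered to ~1e-12 mm, far below the 1e-3 mm
   oracle tolerance used in the tests. One consensus re-evaluation under
   the refined pose recovers points the coarser minimal-solver pose
   misclassified.
3. **Planar ambiguity**: with a single visible marker the homography has
   the classic two-fold pose ambiguity. Both candidates are refined and
   scored; if their reprojection errors differ by less than 5% the frame
   is flagged ambiguous in the estimate's metadata rather than silently
   trusted.

Determinism: all estimation randomness flows from `pose_params()$seed`
through an RNG scope that restores the caller's random state.

## Probe calibration

The crossed-wire phantom provides one known 3D landmark (two wires
crossing at 8 mm depth) and a depth-scale ruler (ten parallel wires at
18 mm, spaced 4 mm). From a single snapshot the solver computes

$$T_{Probe} = T_{Cam2Dod}^{-1}\, T_{Cam2Cal}$$

composed with a pure in-plane translation that puts the wire-cross echo
at its known depth, and the isotropic pixel size from a least-squares
lattice fit of the distal echo positions (scale = 4 mm / mean adjacent
pixel gap; echoes deviating from a line by more than 10% of the gap are
rejected as a collinearity violation). The calibrator frame is *defined*
with its origin at the wire cross and y along the depth direction; the
source protocol leaves this convention unstated, so it is a declared
package choice that reproduces the stated matrix identity. A snapshot
flagged as showing more than one proximal echo (probe pitched or rolled
off the wire plane) is refused outright — no in-plane correction is
attempted, because the landmark correspondence is lost in that case.

The recovered depth must agree with the proximal wire depth within 1 mm
(default), otherwise the snapshot is rejected as depth-inconsistent.

## Trajectory processing and evaluation

* **Filtering** — each translation component passes through a
  Savitzky–Golay filter (default window 15 samples ≈ 0.25 s at 60 Hz,
  polynomial order 3 — a standard smooth-trajectory choice, exposed in
  the configuration); rotations are never filtered. The filter reproduces
  polynomials up to its order exactly, including at the stream edges.
* **Resampling** — the 200 Hz IR reference is resampled onto the 60 Hz
  camera clock, never the reverse: quaternions by SLERP with hemisphere
  alignment (negate one endpoint when their dot product is negative, so
  interpolation takes the shortest arc), translations linearly per
  component. Requests outside the source time range are refused rather
  than extrapolated.
* **Reference chain** — each IR sample yields the cluster pose by
  Kabsch–Umeyama registration of the IR markers' local coordinates onto
  their observed world positions (SVD solution, reflection corrected via
  the smallest singular value's sign, scale fixed at 1 because both
  systems measure metric mm), composed with the single static
  world-from-camera transform.
* **Statistics** — the four ultrasound image corners (FOV 38 mm, depth
  30 mm) are mapped through the candidate and reference chains; the
  signed error vectors are summarized by per-axis mean and *population*
  standard deviation (the 1/N convention, matching the printed defining
  formula literally) plus the Euclidean norms of both triples. An
  `origin` row evaluates cluster-origin translation only, ignoring
  rotation — the interpretation adopted for the source table's footnote
  about discarding the rotational component, which is mathematically odd
  as printed ("multiplying by the null element") and is implemented as
  the translation-only evaluation rather than guessed further.

Frames where pose estimation fails (no detections after dropout, no
RANSAC consensus) are carried as gaps: they are absent from the stream,
and filtering/resampling never see them. Zero-filling would bias the
statistics; the gap semantics is a package contract, since the source
protocol does not state how failed frames were handled.

## The synthetic data generator

The simulator emulates the study conditions at desk scale: a C²-smooth
probe sweep (natural cubic splines through seeded waypoints for
translation; a fixed base orientation composed with three splined small
Euler angles, increments scaled so angular velocity stays under a 30°/s
cap — the slow, constant-velocity regime a careful operator produces);
perspective projection of the self-occlusion-visible marker corners at
60 Hz with isotropic Gaussian pixel noise (default 0.5 px) and
independent per-marker Bernoulli dropout (default 0.1); an IR stream at
200 Hz with 0.2 mm Gaussian noise on 4 tetrahedral cluster markers of
40 mm circumradius (the physical IR cluster's geometry and residual noise
are not documented, so these defaults are declared, not inferred); and a
geometrically consistent calibration snapshot with a 0.1 mm/px simulated
pixel size. The camera defaults to VGA with 600 px focal length, zero
distortion, 400 mm standoff.

What it does **not** model: motion blur, rolling shutter, detector
corner-localization bias, lighting, B-mode speckle or echo-detection
errors, patient/phantom motion, and clock desynchronization beyond an
optional constant offset. Passing tests therefore demonstrate the
correctness of the geometry, estimation and evaluation chain under the
stated noise model — not detector robustness on real video.

## Numerical choices and problem sizes

Orthonormality is validated at 1e-6 on construction (file round-trips
drift) but never silently re-orthonormalized. Quaternions serialize with
$w \ge 0$ (first nonzero component positive when $w = 0$). The DLT null
vector comes from the eigendecomposition of $A^\top A$, adequate for an
initializer that LM always refines. Degenerate inputs fail with typed
conditions (`DegenerateConfiguration`, `NoConsensus`, `BehindCamera`,
`WindowTooLarge`, ...) rather than returning garbage.

The test and acceptance workloads use 5 s sweeps (301 frames) for the
noiseless and stochastic round trips and 1 s sweeps × 5 seeds per
distance for the 300/600/900 mm error profile — sizes chosen so the full
suite exercises every stage at meaningful sample counts while staying
desk-scale. At these sizes the noiseless chain closes below 1e-3 mm,
stochastic errors sit in the sub-millimetre range at 400 mm (the
published experiments, with a real detector and camera, report
millimetre-level norms), and the mean error norm grows monotonically
with camera distance.

## Known limitations

* The marker detector itself is out of scope: observations enter as
  corner pixels with ids (from the bundled simulator or any external
  ArUco detector writing the JSONL format).
* Calibration uses a single snapshot; multi-snapshot least squares and
  temporal calibration are not implemented.
* The pixel scale is isotropic by construction; anisotropic scaling is a
  non-goal.
* Volume compounding (voxelization, interpolation of intensities) is not
  implemented — only the geometric mapping of pixels into 3D.
* Real-data error levels depend on detector quality and camera
  calibration, which the simulator idealizes; the stochastic envelope
  here bounds the geometric pipeline, not a full real-world system.
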