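Package: sonotrack
Title: Optical Six-Degree-of-Freedom Ultrasound Probe Tracking with a
    Fiducial Marker Dodecahedron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for low-cost freehand 3D ultrasound probe tracking with a
    single RGB camera and a dodecahedral cluster of square fiducial (ArUco)
    markers. Provides SE(3) rigid-transform primitives, dodecahedron cluster
    geometry and pinhole camera modelling, robust Perspective-n-Point pose
    estimation with RANSAC and Levenberg-Marquardt refinement (direct and
    transform-concatenation variants), crossed-wire phantom probe calibration,
    Savitzky-Golay trajectory filtering, SLERP resampling, Kabsch-Umeyama
    rigid registration against a reference infrared tracking stream, and
    ultrasound image-corner error statistics. A seeded synthetic camera and
    trajectory simulator makes the whole pipeline testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    signal,
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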