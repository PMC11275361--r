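#' Crossed-wire phantom calibration snapshot
#'
#' Captures everything the probe-calibration solver needs from one frozen
#' instant: the tracked pose of the marker cluster, the tracked pose of the
#' calibrator phantom, and the echo pixel coordinates seen in the
#' ultrasound image. The phantom carries two steel wires crossed at the
#' proximal depth (default 8 mm below the surface) and a distal layer of
#' parallel wires (default 18 mm deep, spaced 4 mm apart); the calibrator
#' frame has its origin at the wire cross with the y-axis along the depth
#' direction.
#'
#' @param T_cam2dod cluster pose at the snapshot (`rigid_transform`,
#'   camera <- cluster).
#' @param T_cam2cal calibrator pose at the snapshot (camera <- calibrator).
#' @param cross_point_px pixel `(u, v)` of the wire-cross echo in the US
#'   image.
#' @param distal_wire_px m x 2 matrix of parallel-wire echo pixels (m >= 2).
#' @param proximal_depth,distal_depth wire depths, mm (distal > proximal).
#' @param wire_spacing distal wire spacing, mm.
#' @param us_image_width_px width of the US image in pixels (the US-frame
#'   x origin sits at the image center column).
#' @param multiple_proximal_echoes flag set when more than one proximal
#'   echo is present in the image (probe pitched or rolled off the wire
#'   plane); such snapshots cannot yield a calibration and are refused.
#' @export
calibration_snapshot <- function(T_cam2dod, T_cam2cal, cross_point_px,
                                 distal_wire_px, proximal_depth = 8,
                                 distal_depth = 18, wire_spacing = 4,
                                 us_image_width_px = 512,
                                 multiple_proximal_echoes = FALSE) {
  stopifnot(is_rigid_transform(T_cam2dod), is_rigid_transform(T_cam2cal))
  distal_wire_px <- rbind(distal_wire_px)
  st_assert(nrow(distal_wire_px) >= 2, "TooFewEchoes",
            "need at least 2 distal wire echoes, got %d", nrow(distal_wire_px))
  st_assert(proximal_depth > 0 && distal_depth > proximal_depth,
            "BadSnapshot", "depths must be positive with distal > proximal")
  structure(list(T_cam2dod = T_cam2dod, T_cam2cal = T_cam2cal,
                 cross_point_px = as.numeric(cross_point_px),
                 distal_wire_px = distal_wire_px,
                 proximal_depth = proximal_depth, distal_depth = distal_depth,
                 wire_spacing = wire_spacing,
                 us_image_width_px = us_image_width_px,
                 multiple_proximal_echoes = isTRUE(multiple_proximal_echoes)),
            class = "calibration_snapshot")
}

#' Cluster-to-calibrator transform from two tracked poses
#'
#' Solves `T_Probe = T_Cam2Dod^-1 . T_Cam2Cal`, the transform from the
#' calibrator (wire-cross) frame into the dodecahedron frame, which
#' satisfies the identity `T_Cam2Dod . T_Probe . T_Cam2Cal^-1 = I`.
#'
#' @param T_cam2dod,T_cam2cal tracked poses (camera <- cluster,
#'   camera <- calibrator).
#' @export
solve_probe_transform <- function(T_cam2dod, T_cam2cal) {
  se3_compose(se3_invert(T_cam2dod), T_cam2cal)
}

#' Ultrasound pixel size from the distal wire echoes
#'
#' The parallel distal wires appear as a row of echoes; a least-squares fit
#' of the echo positions to an equally spaced 1D lattice along their
#' principal axis gives the mean adjacent pixel gap, and
#' `scale = wire_spacing / gap` (mm per pixel, isotropic).
#'
#' @param distal_wire_px m x 2 echo pixels (m >= 2), roughly collinear.
#' @param wire_spacing physical wire spacing, mm.
#' @return pixel size, mm/px.
#' @export
estimate_pixel_scale <- function(distal_wire_px, wire_spacing = 4) {
  P <- rbind(distal_wire_px)
  m <- nrow(P)
  st_assert(m >= 2, "TooFewEchoes", "need at least 2 echoes, got %d", m)
  ctr <- colMeans(P)
  rel <- sweep(P, 2, ctr)
  sv <- svd(rel)
  axis <- sv$v[, 1]
  s <- drop(rel %*% axis)            # position along the principal axis
  perp <- drop(rel %*% sv$v[, 2])
  ord <- order(s)
  s <- s[ord]
  idx <- seq_len(m)
  gap <- stats::coef(stats::lm(s ~ idx))[["idx"]]  # lattice fit
  gap <- abs(gap)
  st_assert(gap > 0, "CollinearityViolation", "echoes are coincident")
  st_assert(max(abs(perp)) <= 0.10 * gap, "CollinearityViolation",
            "echoes deviate from a straight line by more than 10%% of the gap")
  wire_spacing / gap
}

#' In-plane offset between US-image origin and the wire cross
#'
#' Places the wire-cross echo at `proximal_depth` below the transducer
#' surface: `x = (cross_u - image_center_u) * pixel_size`,
#' `y = cross_v * pixel_size`. The recovered depth must agree with the
#' known proximal wire depth within `tolerance`, otherwise the snapshot
#' geometry is inconsistent.
#'
#' @param cross_point_px pixel `(u, v)` of the wire-cross echo.
#' @param pixel_size mm/px.
#' @param proximal_depth known cross depth, mm.
#' @param image_center_u center column of the US image, px.
#' @param tolerance allowed |y - proximal_depth| discrepancy, mm.
#' @return numeric length 2 `(x, y)` offset, mm.
#' @export
image_origin_offset <- function(cross_point_px, pixel_size, proximal_depth = 8,
                                image_center_u = 256, tolerance = 1) {
  st_assert(pixel_size > 0, "BadSnapshot", "pixel_size must be positive")
  x <- (cross_point_px[1] - image_center_u) * pixel_size
  y <- cross_point_px[2] * pixel_size
  st_assert(abs(y - proximal_depth) <= tolerance, "DepthInconsistent",
            "cross echo depth %.2f mm disagrees with the %.2f mm proximal wire (tol %.2f mm)",
            y, proximal_depth, tolerance)
  c(x, y)
}

#' Solve the probe calibration from a snapshot
#'
#' Combines [solve_probe_transform()] (cluster <- calibrator),
#' [estimate_pixel_scale()] and [image_origin_offset()] into the full
#' calibration: the returned `T_probe` maps US-image-frame coordinates
#' (x along the transducer array, y along the beam, z = 0 plane, mm) into
#' the dodecahedron frame, so that
#' `p_cam = T_Cam2Dod . T_probe . p_image`.
#'
#' @param snapshot a [calibration_snapshot()].
#' @return a `probe_calibration`: `T_probe` (`rigid_transform`) and
#'   `pixel_size` (mm/px).
#' @export
calibrate <- function(snapshot) {
  stopifnot(inherits(snapshot, "calibration_snapshot"))
  st_assert(!snapshot$multiple_proximal_echoes, "AmbiguousSnapshot",
            "US image shows multiple proximal echoes (probe pitched/rolled); recapture the snapshot")
  pixel_size <- estimate_pixel_scale(snapshot$distal_wire_px,
                                     snapshot$wire_spacing)
  offset <- image_origin_offset(snapshot$cross_point_px, pixel_size,
                                snapshot$proximal_depth,
                                image_center_u = snapshot$us_image_width_px / 2)
  T_dod_cal <- solve_probe_transform(snapshot$T_cam2dod, snapshot$T_cam2cal)
  # image frame -> calibrator frame is the pure in-plane translation that
  # puts the wire cross at (x, y) = offset in image coordinates, so a point
  # with image coordinates p maps to calibrator coordinates p - offset
  T_cal_from_img <- rigid_transform(diag(3), c(-offset[1], -offset[2], 0))
  structure(list(T_probe = se3_compose(T_dod_cal, T_cal_from_img),
                 pixel_size = pixel_size),
            class = "probe_calibration")
}

#' Read / write probe calibration JSON
#'
#' Schema: `{T_probe: {quat: [w,x,y,z], t: [x,y,z]}, pixel_size}`.
#' @param path file path.
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(T_probe = rigid_transform(quat_to_rot(j$T_probe$quat),
                                           j$T_probe$t),
                 pixel_size = j$pixel_size),
            class = "probe_calibration")
}

#' @rdname read_calibration_json
#' @param cal a `probe_calibration`.
#' @export
write_calibration_json <- function(cal, path) {
  jsonlite::write_json(
    list(T_probe = list(quat = rot_to_quat(cal$T_probe$R), t = cal$T_probe$t),
         pixel_size = cal$pixel_size),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
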