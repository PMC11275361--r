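#' Simulation configuration
#'
#' Bundles everything the synthetic data generator needs: camera, cluster
#' and IR-cluster geometry, the ground-truth probe calibration, sampling
#' rates (RGB video 60 Hz, IR reference 200 Hz), noise levels and the seed.
#' RGB and IR share one clock (clock synchronization is assumed perfect;
#' `clock_offset` exists to exercise resampling robustness).
#'
#' @param duration sweep duration, s.
#' @param rgb_rate RGB camera frame rate, Hz.
#' @param ir_rate IR reference sampling rate, Hz.
#' @param camera a [camera_model()].
#' @param model a [build_dodecahedron()] model.
#' @param ir_cluster an [ir_cluster_model()].
#' @param T_probe_true ground-truth cluster-to-probe transform.
#' @param T_world2cam static world-from-camera pose of the IR system.
#' @param camera_distance nominal cluster distance from the camera along
#'   the optical axis, mm.
#' @param pixel_noise_px isotropic Gaussian corner noise, px (sd).
#' @param ir_noise_mm Gaussian IR marker noise, mm (sd).
#' @param dropout_prob per-marker per-frame Bernoulli dropout probability
#'   (1 drops every marker: all frames come out empty).
#' @param max_ang_vel angular velocity cap of the simulated sweep, deg/s.
#' @param motion_scale scales the sweep's translation and rotation waypoint
#'   increments; 0 freezes the probe at its starting pose.
#' @param clock_offset constant offset added to IR timestamps, s.
#' @param seed integer RNG seed; the whole simulation is deterministic
#'   given the config.
#' @export
sim_config <- function(duration = 5, rgb_rate = 60, ir_rate = 200,
                       camera = default_sim_camera(),
                       model = build_dodecahedron(),
                       ir_cluster = ir_cluster_model(),
                       T_probe_true = default_probe_transform(),
                       T_world2cam = rigid_transform(rot_x(pi / 2), c(500, 200, 300)),
                       camera_distance = 400,
                       pixel_noise_px = 0.5, ir_noise_mm = 0.2,
                       dropout_prob = 0.1, max_ang_vel = 30,
                       motion_scale = 1, clock_offset = 0, seed = 1L) {
  st_assert(duration > 0 && rgb_rate > 0 && ir_rate > 0, "BadConfig",
            "duration and rates must be positive")
  st_assert(pixel_noise_px >= 0 && ir_noise_mm >= 0, "BadConfig",
            "noise levels must be >= 0")
  st_assert(dropout_prob >= 0 && dropout_prob <= 1, "BadConfig",
            "dropout_prob must be in [0, 1]")
  st_assert(motion_scale >= 0, "BadConfig", "motion_scale must be >= 0")
  structure(list(duration = duration, rgb_rate = rgb_rate, ir_rate = ir_rate,
                 camera = camera, model = model, ir_cluster = ir_cluster,
                 T_probe_true = T_probe_true, T_world2cam = T_world2cam,
                 camera_distance = camera_distance,
                 pixel_noise_px = pixel_noise_px, ir_noise_mm = ir_noise_mm,
                 dropout_prob = dropout_prob, max_ang_vel = max_ang_vel,
                 motion_scale = motion_scale,
                 clock_offset = clock_offset, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulated camera (VGA, 600 px focal length, no distortion)
#' @export
default_sim_camera <- function() {
  camera_model(600, 600, 320, 240, dist = c(0, 0, 0, 0, 0),
               width = 640, height = 480)
}

#' Default ground-truth probe transform used by the simulator
#'
#' The probe image plane sits below the cluster (the dodecahedron is fixed
#' to the probe body behind the transducer), with a small fixed rotation.
#' @export
default_probe_transform <- function() {
  rigid_transform(rot_x(-0.25) %*% rot_z(0.1), c(5, 70, -15))
}

#' Simulate a smooth 6-DoF probe sweep
#'
#' Generates a C2-smooth trajectory emulating a careful freehand scan:
#' slow, roughly constant-velocity translation and gentle orientation
#' changes. Translations follow natural cubic splines through seeded
#' waypoints around the nominal standoff; rotations compose a fixed base
#' orientation with three independently splined small Euler angles whose
#' waypoint increments are scaled to respect the angular-velocity cap.
#'
#' @param config a [sim_config()].
#' @return list with `eval(t)` (continuous pose evaluator returning the
#'   cluster pose, camera <- cluster, at any `t` in `[0, duration]`),
#'   `truth_rgb` and `truth_ir` (the truth sampled on each clock's grid).
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dur <- config$duration
  n_wp <- max(4L, ceiling(dur) + 1L)
  tw <- seq(0, dur, length.out = n_wp)
  seg <- if (n_wp > 1) dur / (n_wp - 1) else dur

  ms <- config$motion_scale
  ev <- with_seed(config$seed, {
    # translation waypoints: lateral drift mimicking a longitudinal scan
    wx <- cumsum(c(stats::runif(1, -10, 10), ms * stats::rnorm(n_wp - 1, 4, 6)))
    wy <- cumsum(c(stats::runif(1, -10, 10), ms * stats::rnorm(n_wp - 1, 0, 5)))
    wz <- config$camera_distance +
      cumsum(c(stats::runif(1, -5, 5), ms * stats::rnorm(n_wp - 1, 0, 4)))
    # small-angle Euler waypoints; increments capped well under max_ang_vel
    # (cubic-spline overshoot between waypoints stays below ~1.5x)
    max_step <- config$max_ang_vel * pi / 180 * seg / 2
    ang <- replicate(3, {
      cumsum(c(stats::runif(1, -0.1, 0.1),
               ms * pmax(-max_step,
                         pmin(max_step, stats::rnorm(n_wp - 1, 0, max_step / 2)))))
    })
    R0 <- rot_y(stats::runif(1, -0.4, 0.4)) %*% rot_x(stats::runif(1, -0.4, 0.4))
    list(wx = wx, wy = wy, wz = wz, ang = ang, R0 = R0)
  })
  fx <- stats::splinefun(tw, ev$wx, method = "natural")
  fy <- stats::splinefun(tw, ev$wy, method = "natural")
  fz <- stats::splinefun(tw, ev$wz, method = "natural")
  fa <- lapply(1:3, function(k) stats::splinefun(tw, ev$ang[, k], method = "natural"))

  eval_pose <- function(t) {
    st_assert(t >= 0 && t <= dur + 1e-12, "OutOfRange",
              "t = %.4f outside [0, %.4f]", t, dur)
    R <- ev$R0 %*% rot_x(fa[[1]](t)) %*% rot_y(fa[[2]](t)) %*% rot_z(fa[[3]](t))
    structure(list(R = R, t = c(fx(t), fy(t), fz(t))),
              class = "rigid_transform")
  }
  sample_grid <- function(rate) {
    ts <- seq(0, by = 1 / rate, length.out = floor(dur * rate) + 1)
    pose_stream(ts, lapply(ts, eval_pose), rate_hint = rate)
  }
  list(eval = eval_pose,
       truth_rgb = sample_grid(config$rgb_rate),
       truth_ir = sample_grid(config$ir_rate))
}

#' Simulate RGB marker-corner observations
#'
#' For each RGB frame: determine the self-occlusion-aware visible marker
#' set under the truth pose, drop each marker independently with
#' `dropout_prob`, project the surviving markers' corners and add isotropic
#' Gaussian pixel noise. Frames with zero surviving markers are kept (empty
#' detection lists), mirroring real detector dropouts.
#'
#' @param truth result of [simulate_trajectory()].
#' @param config the same [sim_config()].
#' @return list of [observation_frame()]s at the RGB rate.
#' @export
simulate_observations <- function(truth, config) {
  stream <- truth$truth_rgb
  with_seed(config$seed + 1013L, {
    lapply(seq_along(stream$timestamps), function(i) {
      pose <- stream$poses[[i]]
      ids <- visible_markers(config$camera, pose, config$model)
      if (length(ids) && config$dropout_prob > 0) {
        ids <- ids[stats::runif(length(ids)) >= config$dropout_prob]
      }
      dets <- lapply(ids, function(id) {
        px <- project_points(config$camera, pose,
                             marker_corners_local(config$model, id))
        if (config$pixel_noise_px > 0) {
          px <- px + matrix(stats::rnorm(8, 0, config$pixel_noise_px), 4, 2)
        }
        list(id = id, corners = px)
      })
      observation_frame(stream$timestamps[i], dets)
    })
  })
}

#' Simulate the IR reference marker stream
#'
#' At each IR timestamp the truth pose is applied to the IR cluster's local
#' marker positions, mapped into the world frame by the static
#' `T_world2cam`, and perturbed with Gaussian noise — the per-marker 3D
#' positions a stereophotogrammetric system would report.
#'
#' @param truth result of [simulate_trajectory()].
#' @param config the same [sim_config()].
#' @return an `ir_stream`: `timestamps` (s) and `points` (list of
#'   n_markers x 3 world-frame matrices, mm).
#' @export
simulate_ir_stream <- function(truth, config) {
  stream <- truth$truth_ir
  pts_local <- config$ir_cluster$points_local
  pts <- with_seed(config$seed + 2029L, {
    lapply(stream$poses, function(pose) {
      w <- se3_apply(config$T_world2cam, se3_apply(pose, pts_local))
      if (config$ir_noise_mm > 0) {
        w <- w + matrix(stats::rnorm(length(w), 0, config$ir_noise_mm),
                        nrow(w), 3)
      }
      w
    })
  })
  structure(list(timestamps = stream$timestamps + config$clock_offset,
                 points = pts, labels = config$ir_cluster$labels),
            class = "ir_stream")
}

#' Recover camera-frame cluster poses from an IR stream
#'
#' Per sample, solves the rigid registration from the IR cluster's local
#' marker coordinates to the observed world positions ([kabsch_umeyama()]),
#' giving `T_World2Dod`; composing with the inverse static camera pose
#' yields the reference stream `T_Cam2Dod_IR`.
#'
#' @param ir an `ir_stream`.
#' @param ir_cluster the [ir_cluster_model()] that produced it.
#' @param T_world2cam static world-from-camera pose.
#' @export
ir_to_pose_stream <- function(ir, ir_cluster, T_world2cam) {
  stopifnot(inherits(ir, "ir_stream"))
  inv_w2c <- se3_invert(T_world2cam)
  poses <- lapply(ir$points, function(w) {
    se3_compose(inv_w2c, kabsch_umeyama(ir_cluster$points_local, w))
  })
  pose_stream(ir$timestamps, poses, rate_hint = NA_real_)
}

#' Simulate a crossed-wire calibration snapshot
#'
#' Produces a geometrically consistent snapshot: cluster and calibrator
#' poses satisfying the calibration identity for `config$T_probe_true`, a
#' wire-cross echo at the proximal depth and ten distal echoes spaced
#' `wire_spacing / pixel_size` pixels apart. With zero noise, running
#' [calibrate()] on the result recovers `T_probe_true` exactly.
#'
#' @param config a [sim_config()].
#' @param T_cam2cal_true calibrator pose at the snapshot.
#' @param pixel_size_true simulated US pixel size, mm/px.
#' @param cross_offset_x_mm lateral offset of the wire cross from the image
#'   center, mm.
#' @param pose_noise_mm optional Gaussian translation noise added to both
#'   tracked poses (for sensitivity studies).
#' @param proximal_depth,distal_depth,wire_spacing phantom geometry, mm.
#' @export
simulate_calibration_snapshot <- function(config,
                                          T_cam2cal_true = rigid_transform(rot_y(0.3), c(20, 30, 420)),
                                          pixel_size_true = 0.1,
                                          cross_offset_x_mm = 3,
                                          pose_noise_mm = 0,
                                          proximal_depth = 8,
                                          distal_depth = 18,
                                          wire_spacing = 4) {
  stopifnot(inherits(config, "sim_config"))
  width_px <- 512
  offset <- c(cross_offset_x_mm, proximal_depth)
  cross_px <- c(width_px / 2 + offset[1] / pixel_size_true,
                offset[2] / pixel_size_true)
  gap_px <- wire_spacing / pixel_size_true
  distal_px <- cbind(cross_px[1] + (seq_len(10) - 5.5) * gap_px,
                     distal_depth / pixel_size_true)

  # T_cam2cal = T_cam2dod . T_probe_true . Trans(offset in image plane)
  T_img_from_cal <- rigid_transform(diag(3), c(offset[1], offset[2], 0))
  T_cam2dod <- se3_compose(T_cam2cal_true,
                           se3_compose(se3_invert(T_img_from_cal),
                                       se3_invert(config$T_probe_true)))
  T_cam2cal <- T_cam2cal_true
  if (pose_noise_mm > 0) {
    noise <- with_seed(config$seed + 3047L,
                       stats::rnorm(6, 0, pose_noise_mm))
    T_cam2dod <- rigid_transform(T_cam2dod$R, T_cam2dod$t + noise[1:3])
    T_cam2cal <- rigid_transform(T_cam2cal$R, T_cam2cal$t + noise[4:6])
  }
  calibration_snapshot(T_cam2dod, T_cam2cal, cross_px, distal_px,
                       proximal_depth, distal_depth, wire_spacing,
                       us_image_width_px = width_px)
}

#' Run the full simulator
#'
#' @param config a [sim_config()].
#' @return a `sim_output`: `truth` (evaluator + sampled truth streams),
#'   `rgb_frames`, `ir_stream`, `snapshot`, and `metadata` (seed and key
#'   config values).
#' @export
simulate <- function(config = sim_config()) {
  truth <- simulate_trajectory(config)
  structure(list(truth = truth,
                 rgb_frames = simulate_observations(truth, config),
                 ir_stream = simulate_ir_stream(truth, config),
                 snapshot = simulate_calibration_snapshot(config),
                 metadata = list(seed = config$seed,
                                 duration = config$duration,
                                 rgb_rate = config$rgb_rate,
                                 ir_rate = config$ir_rate,
                                 pixel_noise_px = config$pixel_noise_px,
                                 ir_noise_mm = config$ir_noise_mm,
                                 dropout_prob = config$dropout_prob)),
            class = "sim_output")
}
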