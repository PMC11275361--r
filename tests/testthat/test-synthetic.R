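test_that("the simulator is fully deterministic given its seed", {
  cfg <- sim_config(duration = 1, seed = 11)
  o1 <- simulate(cfg)
  o2 <- simulate(cfg)
  expect_identical(lapply(o1$truth$truth_rgb$poses, `[[`, "t"),
                   lapply(o2$truth$truth_rgb$poses, `[[`, "t"))
  expect_identical(o1$rgb_frames, o2$rgb_frames)
  expect_identical(o1$ir_stream, o2$ir_stream)
})

test_that("zero motion scale freezes the probe", {
  cfg <- sim_config(duration = 1, motion_scale = 0, seed = 2)
  tr <- simulate_trajectory(cfg)
  p0 <- tr$eval(0)
  for (t in c(0.25, 0.5, 0.99)) {
    pt <- tr$eval(t)
    expect_lt(max(abs(pt$R - p0$R)), 1e-12)
    expect_lt(max(abs(pt$t - p0$t)), 1e-9)
  }
})

test_that("angular velocity stays under the configured cap", {
  for (seed in 1:4) {
    cfg <- sim_config(duration = 2, seed = seed)
    tr <- simulate_trajectory(cfg)
    ts <- seq(0, 2, by = 0.005)
    w <- vapply(seq_len(length(ts) - 1), function(i) {
      dR <- t(tr$eval(ts[i])$R) %*% tr$eval(ts[i + 1])$R
      sqrt(sum(rot_to_rotvec(dR)^2)) / 0.005 * 180 / pi
    }, 0)
    expect_lt(max(w), cfg$max_ang_vel)
  }
})

test_that("noiseless observations are exact projections; dropout empties frames", {
  cfg <- sim_config(duration = 0.5, pixel_noise_px = 0, dropout_prob = 0, seed = 3)
  tr <- simulate_trajectory(cfg)
  obs <- simulate_observations(tr, cfg)
  expect_length(obs, floor(0.5 * 60) + 1)
  for (i in c(1, 10, length(obs))) {
    pose <- tr$truth_rgb$poses[[i]]
    for (d in obs[[i]]$detections) {
      expect_equal(d$corners,
                   project_points(cfg$camera, pose,
                                  marker_corners_local(cfg$model, d$id)),
                   tolerance = 1e-12)
    }
  }
  cfg_drop <- sim_config(duration = 0.5, dropout_prob = 1, seed = 3)
  obs_drop <- simulate_observations(tr, cfg_drop)
  expect_true(all(vapply(obs_drop, function(f) length(f$detections) == 0, TRUE)))
})

test_that("observation pixel noise has the configured spread", {
  cfg <- sim_config(duration = 6, pixel_noise_px = 0.5, dropout_prob = 0,
                    motion_scale = 0, seed = 8)
  tr <- simulate_trajectory(cfg)
  obs <- simulate_observations(tr, cfg)
  pose <- tr$truth_rgb$poses[[1]]
  resid <- unlist(lapply(obs, function(fr) {
    unlist(lapply(fr$detections, function(d) {
      d$corners - project_points(cfg$camera, pose,
                                 marker_corners_local(cfg$model, d$id))
    }))
  }))
  expect_gt(length(resid), 1e4)
  expect_equal(stats::sd(resid), 0.5, tolerance = 0.05)
})

test_that("the IR stream is rigid at zero noise and recoverable by registration", {
  cfg <- sim_config(duration = 0.5, ir_noise_mm = 0, seed = 6)
  tr <- simulate_trajectory(cfg)
  ir <- simulate_ir_stream(tr, cfg)
  expect_length(ir$timestamps, floor(0.5 * 200) + 1)
  d1 <- as.numeric(dist(ir$points[[1]]))
  for (i in c(25, 101)) {
    expect_equal(as.numeric(dist(ir$points[[i]])), d1, tolerance = 1e-9)
  }
  ps <- ir_to_pose_stream(ir, cfg$ir_cluster, cfg$T_world2cam)
  for (i in c(1, 50, 101)) {
    expect_lt(max(abs(as_matrix4(ps$poses[[i]]) -
                        as_matrix4(tr$truth_ir$poses[[i]]))), 1e-9)
  }
})

test_that("simulated snapshots carry ten distal echoes spaced 4 mm apart", {
  cfg <- sim_config(seed = 9)
  snap <- simulate_calibration_snapshot(cfg)
  expect_equal(nrow(snap$distal_wire_px), 10)
  gaps <- diff(sort(snap$distal_wire_px[, 1]))
  expect_equal(gaps * 0.1, rep(4, 9), tolerance = 1e-9)
  cal <- calibrate(snap)
  expect_lt(max(abs(cal$T_probe$t - cfg$T_probe_true$t)), 1e-6)
})

test_that("noiseless RGB, IR and truth agree (consistency triangle)", {
  cfg <- sim_config(duration = 0.5, pixel_noise_px = 0, ir_noise_mm = 0,
                    dropout_prob = 0, seed = 12)
  out <- simulate(cfg)
  # RGB route
  est <- pose_concat(out$rgb_frames[[7]], cfg$model, se3_identity(),
                     cfg$camera, pose_params(seed = 1))
  truth <- out$truth$truth_rgb$poses[[7]]
  expect_lt(max(abs(as_matrix4(est$T_cam2dod$T) - as_matrix4(truth))), 1e-6)
  # IR route
  ps <- ir_to_pose_stream(out$ir_stream, cfg$ir_cluster, cfg$T_world2cam)
  i_ir <- which.min(abs(ps$timestamps - out$truth$truth_rgb$timestamps[7]))
  expect_lt(max(abs(as_matrix4(ps$poses[[i_ir]]) -
                      as_matrix4(out$truth$truth_ir$poses[[i_ir]]))), 1e-6)
})
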