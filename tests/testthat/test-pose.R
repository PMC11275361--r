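make_case <- function(T_true = rigid_transform(rot_y(0.4) %*% rot_x(0.2),
                                               c(10, -5, 400))) {
  frame <- noiseless_frame(T_true)
  corr <- augment_correspondences(build_correspondences(frame, fix_model()))
  list(T_true = T_true, frame = frame, corr = corr)
}

test_that("augmentation adds exactly k(k-1)/2 center midpoints", {
  cs <- make_case()
  k <- length(cs$frame$detections)
  expect_gte(k, 2)
  expect_equal(sum(cs$corr$origin == "augmented"), k * (k - 1) / 2)
  expect_equal(sum(cs$corr$origin == "corner"), 4 * k)

  # single marker: no additions
  fr1 <- observation_frame(0, cs$frame$detections[1])
  corr1 <- augment_correspondences(build_correspondences(fr1, fix_model()))
  expect_equal(sum(corr1$origin == "augmented"), 0)

  # hand-checked 3D midpoint of two marker centers
  m <- fix_model()
  ids <- vapply(cs$frame$detections[1:2], function(d) d$id, 0L)
  c1 <- colMeans(marker_corners_local(m, ids[1]))
  c2 <- colMeans(marker_corners_local(m, ids[2]))
  first_aug <- which(cs$corr$origin == "augmented")[1]
  expect_equal(cs$corr$points3d[first_aug, ], (c1 + c2) / 2, tolerance = 1e-12)
})

test_that("noiseless multi-marker pose is recovered to numerical precision", {
  cs <- make_case()
  est <- estimate_pose(cs$corr, fix_camera(), pose_params(seed = 7))
  expect_lt(sqrt(sum((est$T$t - cs$T_true$t)^2)), 1e-3)
  expect_lt(rot_angle_between(est$T$R, cs$T_true$R), 1e-5)
  expect_true(all(est$inlier_mask))
  expect_lt(est$rms_reproj_px, 1e-6)
})

test_that("degenerate correspondence sets are rejected", {
  cam <- fix_camera()
  corr3 <- structure(list(points3d = matrix(stats::rnorm(9), 3, 3),
                          points2d = matrix(stats::rnorm(6, 300, 50), 3, 2),
                          marker_id = rep(1L, 3), origin = rep("corner", 3)),
                     class = "correspondence_set")
  expect_error(estimate_pose(corr3, cam), class = "sonotrack_DegenerateConfiguration")

  collinear <- structure(list(points3d = cbind(seq_len(6), 0, 0),
                              points2d = cbind(seq_len(6) * 10 + 300, 240),
                              marker_id = rep(1L, 6), origin = rep("corner", 6)),
                         class = "correspondence_set")
  expect_error(estimate_pose(collinear, cam),
               class = "sonotrack_DegenerateConfiguration")

  expect_error(pose_direct(observation_frame(0, list()), fix_model(),
                           se3_identity(), cam),
               class = "sonotrack_DegenerateConfiguration")
})

test_that("RANSAC excludes seeded gross outliers and recovers the pose", {
  cs <- make_case()
  set.seed(9)
  p2 <- cs$corr$points2d
  nb <- ceiling(0.2 * nrow(p2))
  bad <- sample(nrow(p2), nb)
  p2[bad, ] <- p2[bad, ] +
    matrix(stats::runif(2 * nb, 30, 120) * sample(c(-1, 1), 2 * nb, TRUE), ncol = 2)
  corr2 <- cs$corr
  corr2$points2d <- p2
  est <- estimate_pose(corr2, fix_camera(), pose_params(seed = 7))
  expect_true(all(!est$inlier_mask[bad]))
  expect_true(all(est$inlier_mask[-bad]))
  expect_lt(sqrt(sum((est$T$t - cs$T_true$t)^2)), 1e-3)
})

test_that("pose estimation is deterministic given the seed", {
  cs <- make_case()
  set.seed(1)
  corrn <- cs$corr
  corrn$points2d <- corrn$points2d + matrix(stats::rnorm(length(corrn$points2d), 0, 0.5), ncol = 2)
  e1 <- estimate_pose(corrn, fix_camera(), pose_params(seed = 42))
  e2 <- estimate_pose(corrn, fix_camera(), pose_params(seed = 42))
  expect_identical(e1$T, e2$T)
  expect_identical(e1$inlier_mask, e2$inlier_mask)
})

test_that("LM refinement never degrades the RANSAC initial inlier rms", {
  set.seed(17)
  for (i in 1:5) {
    T_true <- rigid_transform(random_rotation() %*% rot_x(0),
                              c(stats::runif(2, -20, 20), stats::runif(1, 350, 450)))
    frame <- noiseless_frame(T_true)
    if (length(frame$detections) < 2) next
    corr <- augment_correspondences(build_correspondences(frame, fix_model()))
    corr$points2d <- corr$points2d +
      matrix(stats::rnorm(length(corr$points2d), 0, 0.7), ncol = 2)
    est <- estimate_pose(corr, fix_camera(), pose_params(seed = i))
    expect_lte(est$rms_reproj_px, est$rms_all_px + 1e-12)
  }
})

test_that("estimates are equivariant under a global camera-frame motion", {
  cs <- make_case()
  G <- rigid_transform(rot_z(0.2) %*% rot_x(-0.1), c(30, -20, 50))
  moved <- se3_compose(G, cs$T_true)
  frame_g <- noiseless_frame(moved)
  shared <- intersect(vapply(cs$frame$detections, `[[`, 0L, "id"),
                      vapply(frame_g$detections, `[[`, 0L, "id"))
  sub <- function(fr) observation_frame(0, Filter(function(d) d$id %in% shared,
                                                  fr$detections))
  p <- pose_params(seed = 3)
  e1 <- estimate_pose(augment_correspondences(
    build_correspondences(sub(cs$frame), fix_model())), fix_camera(), p)
  e2 <- estimate_pose(augment_correspondences(
    build_correspondences(sub(frame_g), fix_model())), fix_camera(), p)
  expect_lt(max(abs(as_matrix4(e2$T) - as_matrix4(se3_compose(G, e1$T)))), 1e-6)
})

test_that("direct and concatenation methods agree on noiseless frames", {
  cs <- make_case()
  T_probe <- default_probe_transform()
  p <- pose_params(seed = 5)
  pd <- pose_direct(cs$frame, fix_model(), T_probe, fix_camera(), p)
  pc <- pose_concat(cs$frame, fix_model(), T_probe, fix_camera(), p)
  truth_probe <- se3_compose(cs$T_true, T_probe)
  expect_lt(sqrt(sum((pd$T$t - truth_probe$t)^2)), 1e-3)
  expect_lt(max(abs(as_matrix4(pd$T) - as_matrix4(pc$T_cam2probe))), 1e-6)
  # with identity calibration both reduce to the cluster pose
  pd_i <- pose_direct(cs$frame, fix_model(), se3_identity(), fix_camera(), p)
  pc_i <- pose_concat(cs$frame, fix_model(), se3_identity(), fix_camera(), p)
  expect_lt(max(abs(as_matrix4(pd_i$T) - as_matrix4(pc_i$T_cam2dod$T))), 1e-9)
})

test_that("a single visible marker still yields the pose (planar PnP)", {
  cs <- make_case()
  fr1 <- observation_frame(0, cs$frame$detections[1])
  est <- estimate_pose(augment_correspondences(
    build_correspondences(fr1, fix_model())), fix_camera(), pose_params(seed = 2))
  expect_lt(sqrt(sum((est$T$t - cs$T_true$t)^2)), 1e-3)
  expect_equal(est$n_points, 4)
})
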