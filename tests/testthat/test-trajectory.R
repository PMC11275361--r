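make_stream <- function(n = 41, dt = 1 / 60, fun = NULL) {
  ts <- (seq_len(n) - 1) * dt
  poses <- lapply(ts, function(t) {
    tr <- if (is.null(fun)) c(10 * t, -5 * t, 400 + 20 * t) else fun(t)
    rigid_transform(rot_z(0.3 * t) %*% rot_x(0.1 * t), tr)
  })
  pose_stream(ts, poses, rate_hint = 1 / dt)
}

test_that("pose streams validate their invariants", {
  expect_error(pose_stream(c(0, 0.1, 0.05), replicate(3, se3_identity(), simplify = FALSE)),
               class = "sonotrack_NonMonotoneTimestamps")
  expect_error(pose_stream(numeric(0), list()), class = "sonotrack_BadStream")
})

test_that("Savitzky-Golay filtering reproduces polynomials and spares rotations", {
  s <- make_stream(40)
  # constant translations unchanged
  s_const <- make_stream(40, fun = function(t) c(1, 2, 3))
  f_const <- savgol_translations(s_const, 15, 3)
  expect_equal(do.call(rbind, lapply(f_const$poses, `[[`, "t")),
               matrix(rep(c(1, 2, 3), each = 40), 40), tolerance = 1e-12)

  # cubic translations reproduced exactly (including edges)
  cubic <- function(t) c(2 + 3 * t - 1.5 * t^2 + 0.7 * t^3,
                         -1 + t^2, 400 + t - t^3)
  s_cubic <- make_stream(40, fun = cubic)
  f_cubic <- savgol_translations(s_cubic, 15, 3)
  for (i in seq_along(f_cubic$poses)) {
    expect_equal(f_cubic$poses[[i]]$t, s_cubic$poses[[i]]$t, tolerance = 1e-9)
    # rotations bit-identical
    expect_identical(f_cubic$poses[[i]]$R, s_cubic$poses[[i]]$R)
  }
  expect_identical(f_cubic$timestamps, s_cubic$timestamps)

  expect_error(savgol_translations(make_stream(9), 15, 3),
               class = "sonotrack_WindowTooLarge")
  expect_error(savgol_translations(s, 14, 3), class = "sonotrack_WindowTooLarge")
})

test_that("resampling interpolates with SLERP and hits source samples exactly", {
  # two-pose stream: I at t=0, Rz(90 deg) at t=1; midpoint must be Rz(45 deg)
  s2 <- pose_stream(c(0, 1), list(se3_identity(),
                                  rigid_transform(rot_z(pi / 2), c(10, 0, 0))))
  mid <- resample_stream(s2, 0.5)
  expect_lt(max(abs(mid$poses[[1]]$R - rot_z(pi / 4))), 1e-9)
  expect_equal(mid$poses[[1]]$t, c(5, 0, 0))

  s <- make_stream(31)
  at_src <- resample_stream(s, s$timestamps[c(4, 17)])
  expect_identical(at_src$poses[[1]], s$poses[[4]])
  expect_identical(at_src$poses[[2]], s$poses[[17]])

  expect_error(resample_stream(s, max(s$timestamps) + 1),
               class = "sonotrack_OutOfRange")

  # 200 Hz over 1 s (201 samples) resampled onto the 60 Hz grid -> 61 samples
  ts200 <- seq(0, 1, by = 1 / 200)
  s200 <- pose_stream(ts200, lapply(ts200, function(t)
    rigid_transform(rot_z(t), c(t, 0, 0))))
  ts60 <- seq(0, 1, by = 1 / 60)
  s60 <- resample_stream(s200, ts60)
  expect_length(s60$timestamps, floor(1.0 * 60) + 1)

  # resample-then-subsample at source timestamps is exact
  back <- resample_stream(s, s$timestamps)
  for (i in seq_along(s$poses)) expect_identical(back$poses[[i]], s$poses[[i]])
})

test_that("Kabsch-Umeyama recovers exact rigid motions and is locally optimal", {
  set.seed(19)
  P <- matrix(stats::rnorm(30, 0, 50), 10, 3)
  expect_lt(max(abs(as_matrix4(kabsch_umeyama(P, P)) - diag(4))), 1e-9)

  for (i in 1:20) {
    G <- random_transform()
    est <- kabsch_umeyama(P, se3_apply(G, P))
    expect_lt(max(abs(as_matrix4(est) - as_matrix4(G))), 1e-9)
    expect_gt(det(est$R), 0)
  }

  # noisy case: solution residual beats 1000 random perturbations of itself
  Q <- se3_apply(random_transform(), P) + matrix(stats::rnorm(30, 0, 0.5), 10, 3)
  est <- kabsch_umeyama(P, Q)
  res <- function(T1) sum((se3_apply(T1, P) - Q)^2)
  r0 <- res(est)
  for (i in 1:1000) {
    d <- stats::rnorm(6, 0, 0.01)
    Tp <- rigid_transform(rotvec_to_rot(d[1:3]) %*% est$R, est$t + d[4:6])
    expect_gte(res(Tp), r0 - 1e-12)
  }

  expect_error(kabsch_umeyama(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
               class = "sonotrack_DegenerateConfiguration")
})

test_that("the reference chain composes a single static camera pose", {
  s <- make_stream(11)
  expect_equal(reference_chain(se3_identity(), s)$poses, s$poses)
  G <- rigid_transform(rot_x(pi / 2), c(500, 200, 300))
  chained <- reference_chain(G, s)
  back <- reference_chain(se3_invert(G), chained)
  for (i in seq_along(s$poses)) {
    expect_lt(max(abs(as_matrix4(back$poses[[i]]) - as_matrix4(s$poses[[i]]))), 1e-9)
  }
  expect_identical(chained$timestamps, s$timestamps)
})

test_that("image corners follow the FOV/depth formulas", {
  cc <- image_corners(us_image_spec(fov = 38, depth = 30))
  expect_equal(cc, rbind(c(19, 0, 0), c(19, 30, 0), c(-19, 30, 0), c(-19, 0, 0)))
  # degenerate spec collapses to the origin
  expect_equal(image_corners(us_image_spec(0, 0)), matrix(0, 4, 3))
  # rectangle area = FOV * depth
  v1 <- cc[2, ] - cc[1, ]; v2 <- cc[4, ] - cc[1, ]
  expect_equal(sqrt(sum(sonotrack:::cross3(v1, v2)^2)), 38 * 30)
})

test_that("corner mapping respects each method's transform chain", {
  spec <- us_image_spec()
  s <- pose_stream(0, list(se3_identity()))
  expect_equal(map_corners("direct", s, spec = spec)[[1]], image_corners(spec))
  expect_equal(map_corners("concat", s, se3_identity(), spec)[[1]],
               image_corners(spec))

  # origin method ignores the rotational component entirely
  T1 <- rigid_transform(rot_z(1.2) %*% rot_y(-0.4), c(7, -3, 2))
  s1 <- pose_stream(0, list(T1))
  expect_equal(map_corners("origin", s1, spec = spec)[[1]], matrix(T1$t, 1, 3))

  # direct on the probe pose equals concat on the cluster pose
  T_probe <- default_probe_transform()
  s_probe <- pose_stream(0, list(se3_compose(T1, T_probe)))
  expect_equal(map_corners("direct", s_probe, spec = spec)[[1]],
               map_corners("concat", s1, T_probe, spec)[[1]], tolerance = 1e-12)
})

test_that("error statistics use the population convention and norm identity", {
  x <- list(rbind(c(1, 2, 3), c(4, 5, 6)))
  z <- error_stats(x, x)
  expect_equal(z$mean, c(0, 0, 0))
  expect_equal(z$std, c(0, 0, 0))
  expect_equal(z$mean_norm, 0)

  cand <- rbind(c(1, 0, 0), c(3, 0, 0), c(5, 0, 0))
  ref <- matrix(0, 3, 3)
  s <- error_stats(cand, ref)
  expect_equal(s$n, 3)
  expect_equal(s$mean, c(3, 0, 0))
  # population std: sqrt(mean((1,3,5) - 3)^2) = sqrt(8/3)
  expect_equal(s$std, c(sqrt(8 / 3), 0, 0))
  expect_equal(s$mean_norm, sqrt(sum(s$mean^2)), tolerance = 1e-12)
  expect_equal(s$std_norm, sqrt(sum(s$std^2)), tolerance = 1e-12)

  expect_error(error_stats(cand, ref[1:2, ]), class = "sonotrack_ShapeMismatch")
})

test_that("pixel mapping lands corner pixels on the image corners and stays planar", {
  spec <- us_image_spec(fov = 38, depth = 30, pixel_size = 38)
  # 2x2 grid with pixel_size = FOV: pixels at x in {19, -19}, y in {0, 38}
  pts <- map_image_pixels(se3_identity(), se3_identity(), spec, 2, 2)
  expect_equal(pts[1, ], c(19, 0, 0))
  expect_equal(pts[2, ], c(-19, 0, 0))
  expect_equal(pts[3, ], c(19, 38, 0))

  spec2 <- us_image_spec(fov = 38, depth = 30, pixel_size = 0.5)
  T1 <- rigid_transform(rot_y(0.7) %*% rot_x(0.2), c(12, -8, 350))
  pts2 <- map_image_pixels(T1, default_probe_transform(), spec2, 20, 30)
  ctr <- colMeans(pts2)
  sv <- svd(sweep(pts2, 2, ctr))$d
  expect_lt(sv[3], 1e-9)  # rigid image of a plane stays a plane
})
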