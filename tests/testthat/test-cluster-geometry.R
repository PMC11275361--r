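test_that("the cluster has 12 faces, 48 corners, and exact face geometry", {
  m <- fix_model()
  expect_length(m$faces, 12)
  corners <- do.call(rbind, lapply(m$faces, `[[`, "corners_local"))
  expect_equal(nrow(corners), 48)
  expect_length(unique(vapply(m$faces, `[[`, 0L, "marker_id")), 12)

  for (f in m$faces) {
    cc <- f$corners_local
    # marker edge length 25 mm between consecutive corners
    d <- vapply(1:4, function(i) sqrt(sum((cc[i, ] - cc[(i %% 4) + 1, ])^2)), 0)
    expect_equal(d, rep(25, 4), tolerance = 1e-9)
    # coplanar with the face, centroid on the face plane
    off <- drop(cc %*% f$outward_normal) - sum(f$outward_normal * f$center)
    expect_lt(max(abs(off)), 1e-9)
    # equal-magnitude plane offset: inradius
    expect_equal(abs(sum(f$outward_normal * f$center)),
                 dodecahedron_inradius(m$edge_length), tolerance = 1e-9)
  }
})

test_that("face-plane distance matches the closed-form inradius", {
  # (a/2) * sqrt((25 + 11*sqrt(5)) / 10), a = 31
  expect_equal(dodecahedron_inradius(31), 31 * 1.113516, tolerance = 1e-5)
  m <- build_dodecahedron(edge_length = 20, marker_size = 12, marker_inset = 1)
  d <- vapply(m$faces, function(f) abs(sum(f$outward_normal * f$center)), 0)
  expect_equal(d, rep(dodecahedron_inradius(20), 12), tolerance = 1e-9)
})

test_that("markers that cannot fit the pentagon are rejected", {
  expect_error(build_dodecahedron(edge_length = 20),
               class = "sonotrack_MarkerDoesNotFit")
  expect_silent(build_dodecahedron(edge_length = 31))
})

test_that("construction is deterministic and ids are assignable", {
  expect_identical(build_dodecahedron(), build_dodecahedron())
  m <- build_dodecahedron(id_assignment = 101:112)
  expect_setequal(vapply(m$faces, `[[`, 0L, "marker_id"), 101:112)
  expect_error(build_dodecahedron(id_assignment = c(0:10, 0)),
               class = "sonotrack_BadGeometry")
})

test_that("marker corner lookup honours ids and rejects unknown ones", {
  m <- fix_model()
  cc <- marker_corners_local(m, 0L)
  expect_equal(dim(cc), c(4L, 3L))
  expect_error(marker_corners_local(m, 99L),
               class = "sonotrack_UnknownMarkerId")
})

test_that("pinhole projection matches hand-computed pixels", {
  cam <- fix_camera()
  expect_equal(drop(project_points(cam, se3_identity(), c(0, 0, 500))),
               c(320, 240))
  # u = fx * x / z + cx = 600 * 50 / 500 + 320 = 380
  expect_equal(drop(project_points(cam, se3_identity(), c(50, 0, 500))),
               c(380, 240))
  expect_error(project_points(cam, se3_identity(), c(0, 0, -10)),
               class = "sonotrack_BehindCamera")
})

test_that("distortion round-trips through undistortion", {
  cam <- camera_model(600, 580, 320, 240,
                      dist = c(-0.05, 0.01, 0.001, -0.002, 0.001))
  set.seed(2)
  xy <- matrix(stats::runif(40, -0.3, 0.3), 20, 2)
  xd <- sonotrack:::distort_normalized(cam, xy)
  expect_lt(max(abs(sonotrack:::undistort_normalized(cam, xd) - xy)), 1e-9)
})

test_that("projection commutes with rigid pre-transformation", {
  cam <- fix_camera()
  m <- fix_model()
  T1 <- rigid_transform(rot_y(0.3), c(5, -10, 450))
  pts <- marker_corners_local(m, 3L)
  expect_equal(project_points(cam, T1, pts),
               project_points(cam, se3_identity(), se3_apply(T1, pts)),
               tolerance = 1e-9)
})

test_that("self-occlusion visibility stays within the convexity bound", {
  cam <- fix_camera()
  m <- fix_model()
  # a face turned straight at the camera is visible
  n1 <- m$faces[[1]]$outward_normal
  # rotate face-1 normal onto -z (pointing back at the camera)
  v <- sonotrack:::cross3(n1, c(0, 0, -1))
  th <- acos(sum(n1 * c(0, 0, -1)))
  R <- rotvec_to_rot(v / sqrt(sum(v^2)) * th)
  ids <- visible_markers(cam, rigid_transform(R, c(0, 0, 400)), m)
  expect_true(m$faces[[1]]$marker_id %in% ids)

  set.seed(31)
  for (i in 1:1000) {
    T1 <- rigid_transform(random_rotation(),
                          c(stats::runif(2, -30, 30), stats::runif(1, 350, 500)))
    nv <- length(visible_markers(cam, T1, m))
    expect_gte(nv, 1)
    expect_lte(nv, 6)
  }

  # cluster fully outside the image frustum: no visible markers
  expect_length(visible_markers(cam, rigid_transform(diag(3), c(5000, 0, 400)), m), 0)
  expect_error(visible_markers(cam, rigid_transform(diag(3), c(0, 0, -400)), m),
               class = "sonotrack_BehindCamera")
})

test_that("marker corners stay strictly inside their pentagon", {
  m <- fix_model()
  for (f in m$faces) {
    P <- m$vertices[f$vertex_idx, , drop = FALSE]
    for (k in 1:5) {
      a <- P[k, ]; b <- P[(k %% 5) + 1, ]
      inward <- sonotrack:::cross3(f$outward_normal, b - a)
      margins <- apply(f$corners_local, 1, function(p) sum((p - a) * inward))
      expect_true(all(margins > 0))
    }
  }
})

test_that("cluster geometry JSON round-trips", {
  m <- build_dodecahedron(id_assignment = c(5L, 0:4, 6:11))
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_json(m, path)
  m2 <- read_cluster_json(path)
  expect_equal(m2$edge_length, m$edge_length)
  for (i in seq_along(m$faces)) {
    expect_equal(m2$faces[[i]]$marker_id, m$faces[[i]]$marker_id)
    expect_lt(max(abs(m2$faces[[i]]$corners_local - m$faces[[i]]$corners_local)),
              1e-6)
  }
})

test_that("IR cluster model rejects collinear marker sets", {
  expect_silent(ir_cluster_model())
  expect_error(ir_cluster_model(cbind(1:5, 0, 0)),
               class = "sonotrack_BadGeometry")
})
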