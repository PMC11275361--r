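#' Per-frame marker observations
#'
#' One RGB frame's detections: marker ids and their four ordered corner
#' pixels (same corner convention as [marker_corners_local()]).
#'
#' @param timestamp frame time, seconds.
#' @param detections list of `list(id = <integer>, corners = <4 x 2 matrix>)`.
#' @export
observation_frame <- function(timestamp, detections = list()) {
  st_assert(is.finite(timestamp), "BadObservation", "timestamp must be finite")
  ids <- vapply(detections, function(d) as.integer(d$id), 0L)
  st_assert(!anyDuplicated(ids), "DuplicateMarkerId",
            "marker ids must be unique within a frame")
  detections <- lapply(detections, function(d) {
    m <- matrix(as.numeric(unlist(d$corners)),
                ncol = 2, byrow = !is.matrix(d$corners))
    if (is.matrix(d$corners)) m <- unname(as.matrix(d$corners))
    st_assert(nrow(m) == 4 && ncol(m) == 2 && all(is.finite(m)),
              "BadObservation", "each detection needs 4 finite corner pixels")
    list(id = as.integer(d$id), corners = m)
  })
  structure(list(timestamp = timestamp, detections = detections),
            class = "observation_frame")
}

#' Build 2D-3D correspondences from a frame
#'
#' Pairs each detected marker corner (2D pixels) with its model coordinates
#' expressed in `object frame = T_obj_from_dod` applied to the cluster frame.
#' For the direct pose method the object frame is the probe frame
#' (`T_obj_from_dod = se3_invert(T_probe)`); for the concatenation method it
#' is the cluster frame itself.
#'
#' @param frame an [observation_frame()].
#' @param model a [build_dodecahedron()] model.
#' @param T_obj_from_dod transform from cluster frame to the desired object
#'   frame.
#' @return a `correspondence_set`: `points3d` (n x 3 mm), `points2d`
#'   (n x 2 px), `marker_id` (per point), `origin` ("corner"/"augmented").
#' @export
build_correspondences <- function(frame, model, T_obj_from_dod = se3_identity()) {
  stopifnot(inherits(frame, "observation_frame"))
  p3 <- NULL; p2 <- NULL; mid <- integer(0)
  for (d in frame$detections) {
    corners <- se3_apply(T_obj_from_dod, marker_corners_local(model, d$id))
    p3 <- rbind(p3, corners)
    p2 <- rbind(p2, d$corners)
    mid <- c(mid, rep(d$id, 4))
  }
  structure(list(points3d = p3, points2d = p2, marker_id = mid,
                 origin = rep("corner", length(mid))),
            class = "correspondence_set")
}

#' Augment correspondences with pairwise marker-center midpoints
#'
#' For every unordered pair of detected markers, appends one extra
#' correspondence: the midpoint of the two markers' center points, computed
#' consistently in the 3D object frame and in the 2D pixel frame (a marker's
#' center is the mean of its four corners in each space). With `k` detected
#' markers exactly `k * (k - 1) / 2` points are added, tagged `"augmented"`;
#' the original corner points are unchanged.
#'
#' Because image-space averaging and perspective projection do not commute,
#' an augmented point also records the eight 3D corners of its two parent
#' markers: the reprojection model predicts its pixel as the mean of the
#' parents' projected corners, mirroring exactly how the observed midpoint
#' was formed from detected corner pixels, so augmented residuals vanish
#' under the true pose on noiseless data. The plain 3D midpoint is still
#' what the minimal RANSAC solvers consume.
#'
#' @param corr a `correspondence_set` of corner points.
#' @export
augment_correspondences <- function(corr) {
  stopifnot(inherits(corr, "correspondence_set"))
  ids <- unique(corr$marker_id[corr$origin == "corner"])
  k <- length(ids)
  if (is.null(corr$aug_parents)) {
    corr$aug_parents <- vector("list", length(corr$origin))
  }
  if (k < 2) return(corr)
  corners3 <- lapply(ids, function(i) {
    corr$points3d[corr$marker_id == i & corr$origin == "corner", , drop = FALSE]
  })
  centers3 <- t(vapply(corners3, colMeans, numeric(3)))
  centers2 <- t(vapply(ids, function(i) {
    colMeans(corr$points2d[corr$marker_id == i & corr$origin == "corner", , drop = FALSE])
  }, numeric(2)))
  for (a in seq_len(k - 1)) {
    for (b in seq.int(a + 1, k)) {
      corr$points3d <- rbind(corr$points3d, (centers3[a, ] + centers3[b, ]) / 2)
      corr$points2d <- rbind(corr$points2d, (centers2[a, ] + centers2[b, ]) / 2)
      corr$marker_id <- c(corr$marker_id, NA_integer_)
      corr$origin <- c(corr$origin, "augmented")
      corr$aug_parents <- c(corr$aug_parents,
                            list(rbind(corners3[[a]], corners3[[b]])))
    }
  }
  corr
}

#' Default robust pose-estimation parameters
#'
#' @param ransac_iters maximum RANSAC iterations.
#' @param reproj_threshold_px inlier pixel reprojection threshold.
#' @param min_inliers minimum consensus size for a valid model.
#' @param confidence early-exit confidence for the adaptive iteration bound.
#' @param seed RNG seed making the estimate deterministic.
#' @param lm_maxit,lm_ftol Levenberg-Marquardt iteration cap and relative
#'   cost-change tolerance.
#' @export
pose_params <- function(ransac_iters = 500L, reproj_threshold_px = 2.0,
                        min_inliers = 4L, confidence = 0.99, seed = 1L,
                        lm_maxit = 100L, lm_ftol = 1e-10) {
  list(ransac_iters = as.integer(ransac_iters),
       reproj_threshold_px = reproj_threshold_px,
       min_inliers = as.integer(min_inliers), confidence = confidence,
       seed = as.integer(seed), lm_maxit = as.integer(lm_maxit),
       lm_ftol = lm_ftol)
}

# ---- PnP initializers (normalized, undistorted image coordinates) --------

# Direct Linear Transform for >= 6 non-coplanar correspondences.
pnp_dlt <- function(p3, xy) {
  n <- nrow(p3)
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    X <- c(p3[i, ], 1)
    A[2 * i - 1, ] <- c(X, rep(0, 4), -xy[i, 1] * X)
    A[2 * i, ] <- c(rep(0, 4), X, -xy[i, 2] * X)
  }
  v <- null_vector(A)
  P <- matrix(v, 3, 4, byrow = TRUE)
  # fix global sign so points land in front of the camera
  z <- cbind(p3, 1) %*% P[3, ]
  if (median(z) < 0) P <- -P
  M <- P[, 1:3]
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  scale <- mean(sv$d)
  tryCatch(rigid_transform(R, P[, 4] / scale),
           error = function(e) NULL)
}

# Plane-to-image homography decomposition for coplanar points (>= 4).
# Returns up to two candidate poses (the classic planar two-fold ambiguity).
pnp_planar <- function(p3, xy) {
  ctr <- colMeans(p3)
  sv <- svd(sweep(p3, 2, ctr))
  B <- sv$v  # columns: in-plane e1, e2, normal
  if (det(B) < 0) B[, 3] <- -B[, 3]
  uv <- sweep(p3, 2, ctr) %*% B[, 1:2]

  n <- nrow(p3)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(uv[i, ], 1)
    A[2 * i - 1, ] <- c(X, rep(0, 3), -xy[i, 1] * X)
    A[2 * i, ] <- c(rep(0, 3), X, -xy[i, 2] * X)
  }
  h <- null_vector(A)
  H <- matrix(h, 3, 3, byrow = TRUE)
  lam <- 2 / (vnorm(H[, 1]) + vnorm(H[, 2]))
  if ((H[3, ] %*% c(0, 0, 1))[1] < 0) lam <- -lam  # plane origin in front
  r1 <- lam * H[, 1]; r2 <- lam * H[, 2]; t <- lam * H[, 3]
  if (t[3] < 0) { r1 <- -r1; r2 <- -r2; t <- -t }
  Rm <- cbind(r1, r2, cross3(r1, r2))
  sv2 <- svd(Rm)
  R <- sv2$u %*% t(sv2$v)
  if (det(R) < 0) R <- sv2$u %*% diag(c(1, 1, -1)) %*% t(sv2$v)

  # camera <- object = (camera <- plane) o (plane <- object)
  T_plane_obj <- rigid_transform(t(B), drop(-t(B) %*% ctr))
  T1 <- tryCatch(se3_compose(rigid_transform(R, t), T_plane_obj),
                 error = function(e) NULL)
  if (is.null(T1)) return(list())

  # second candidate: reflect the plane normal across the line of sight
  c_cam <- se3_apply(T1, ctr)
  v <- c_cam / vnorm(c_cam)
  m <- drop(T1$R %*% B[, 3])
  u <- cross3(v, m)
  if (vnorm(u) < 1e-6) return(list(T1))
  u <- u / vnorm(u)
  th <- acos(max(-1, min(1, sum(m * v))))
  Rfix <- rotvec_to_rot(-2 * th * u)
  R2 <- Rfix %*% T1$R
  T2 <- tryCatch(rigid_transform(R2, c_cam - drop(R2 %*% ctr)),
                 error = function(e) NULL)
  if (is.null(T2)) list(T1) else list(T1, T2)
}

# Dispatch: coplanar samples go through the homography route, others DLT.
pnp_minimal <- function(p3, xy) {
  sv <- svd(sweep(p3, 2, colMeans(p3)))$d
  if (sv[3] < 1e-6 * max(sv[1], 1)) {
    if (nrow(p3) < 4) return(list())
    pnp_planar(p3, xy)
  } else {
    if (nrow(p3) < 6) return(list())
    cand <- pnp_dlt(p3, xy)
    if (is.null(cand)) list() else list(cand)
  }
}

# Smallest-eigenvalue right null vector of A (homogeneous DLT systems).
null_vector <- function(A) {
  e <- eigen(crossprod(A), symmetric = TRUE)
  e$vectors[, ncol(e$vectors)]
}

# Subset the point rows of a correspondence-like list.
corr_rows <- function(corr, idx) {
  prepare_corr(list(
    points3d = corr$points3d[idx, , drop = FALSE],
    points2d = corr$points2d[idx, , drop = FALSE],
    aug_parents = if (is.null(corr$aug_parents)) NULL else corr$aug_parents[idx]))
}

# Pre-stack augmented parent corners so repeated reprojection calls avoid
# per-call rbinds.
prepare_corr <- function(corr) {
  if (is.null(corr$aug_parents)) return(corr)
  aug <- which(!vapply(corr$aug_parents, is.null, TRUE))
  corr$aug_rows <- aug
  if (length(aug)) {
    corr$aug_stack <- do.call(rbind, corr$aug_parents[aug])
    corr$aug_grp <- rep(seq_along(aug),
                        vapply(corr$aug_parents[aug], nrow, 0L))
    corr$aug_cnt <- tabulate(corr$aug_grp)
  }
  corr
}

# Predicted pixel positions under pose (R, t). Corner rows are projected
# directly; an augmented row predicts the mean of its parents' projected
# corners (image-space averaging, matching how it was observed).
predict_pixels <- function(camera, R, t, corr) {
  proj <- function(p3) {
    pc <- sweep(p3 %*% t(R), 2, t, "+")
    bad <- pc[, 3] <= 0
    z <- pmax(pc[, 3], 1e-9)
    xy <- distort_normalized(camera, pc[, 1:2, drop = FALSE] / z)
    px <- cbind(camera$fx * xy[, 1] + camera$cx, camera$fy * xy[, 2] + camera$cy)
    px[bad, ] <- 1e6  # drive such poses out during optimization
    px
  }
  if (is.null(corr$aug_rows) && !is.null(corr$aug_parents)) {
    corr <- prepare_corr(corr)
  }
  px <- proj(corr$points3d)
  aug <- corr$aug_rows
  if (length(aug)) {
    stacked <- proj(corr$aug_stack)
    px[aug, 1] <- rowsum(stacked[, 1], corr$aug_grp) / corr$aug_cnt
    px[aug, 2] <- rowsum(stacked[, 2], corr$aug_grp) / corr$aug_cnt
  }
  px
}

# Pixel reprojection errors of pose T for a correspondence set.
reproj_errors <- function(camera, T, corr) {
  e <- predict_pixels(camera, T$R, T$t, corr) - corr$points2d
  sqrt(rowSums(e^2))
}

# SO(3) right Jacobian: d/dv of Exp(v + dv) = Exp(v) Exp(Jr(v) dv).
so3_right_jacobian <- function(v) {
  th <- vnorm(v)
  K <- skew3(v)
  if (th < 1e-8) return(diag(3) - 0.5 * K + K %*% K / 6)
  diag(3) - (1 - cos(th)) / th^2 * K + (th - sin(th)) / th^3 * (K %*% K)
}

# Analytic Jacobian of the stacked pixel residuals w.r.t. (rvec, t) for the
# distortion-free pinhole. Rows follow as.numeric(px - obs): all u's first,
# then all v's. Augmented rows average their parents' per-point Jacobians.
reproj_jacobian <- function(camera, par, corr) {
  R <- rotvec_to_rot(par[1:3])
  Jr <- so3_right_jacobian(par[1:3])
  point_jac <- function(p_local) {
    pc <- drop(R %*% p_local) + par[4:6]
    z <- max(pc[3], 1e-9)
    # d pc / d (rvec, t): right-perturbation chain for the rotation block
    dpc <- cbind(-R %*% skew3(p_local) %*% Jr, diag(3))
    du <- camera$fx * (dpc[1, ] / z - pc[1] * dpc[3, ] / z^2)
    dv <- camera$fy * (dpc[2, ] / z - pc[2] * dpc[3, ] / z^2)
    rbind(du, dv)
  }
  n <- nrow(corr$points3d)
  Ju <- matrix(0, n, 6); Jv <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    parents <- if (is.null(corr$aug_parents)) NULL else corr$aug_parents[[i]]
    if (is.null(parents)) {
      J <- point_jac(corr$points3d[i, ])
    } else {
      J <- Reduce(`+`, lapply(seq_len(nrow(parents)),
                              function(k) point_jac(parents[k, ]))) / nrow(parents)
    }
    Ju[i, ] <- J[1, ]; Jv[i, ] <- J[2, ]
  }
  rbind(Ju, Jv)
}

# Levenberg-Marquardt refinement of (axis-angle, translation) minimizing
# summed squared pixel reprojection error over the given subset.
lm_refine <- function(camera, T0, corr, params) {
  par0 <- c(rot_to_rotvec(T0$R), T0$t)
  resid <- function(par) {
    as.numeric(predict_pixels(camera, rotvec_to_rot(par[1:3]), par[4:6], corr) -
                 corr$points2d)
  }
  jac <- if (all(camera$dist == 0)) {
    function(par) reproj_jacobian(camera, par, corr)
  } else NULL  # distorted model: numeric differentiation
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = resid, jac = jac,
                       control = minpack.lm::nls.lm.control(
                         maxiter = params$lm_maxit, ftol = params$lm_ftol,
                         ptol = 1e-12, gtol = 0)),
    error = function(e) NULL)
  if (is.null(fit)) return(T0)
  T1 <- tryCatch(rigid_transform(rotvec_to_rot(fit$par[1:3]), fit$par[4:6]),
                 error = function(e) NULL)
  if (is.null(T1)) return(T0)
  # never return a pose worse than the initializer on this subset
  if (mean(reproj_errors(camera, T1, corr)^2) <=
      mean(reproj_errors(camera, T0, corr)^2)) T1 else T0
}

#' Robust pose from 2D-3D correspondences (RANSAC + Levenberg-Marquardt)
#'
#' An initial camera-from-object pose is found by RANSAC over minimal
#' Perspective-n-Point solutions (plane-homography decomposition for
#' coplanar samples, DLT otherwise); the points it selects as inliers under
#' the pixel reprojection threshold are then used to refine the pose with
#' the Levenberg-Marquardt scheme, minimizing the summed squared
#' reprojection error over inliers only. Deterministic for a fixed
#' `params$seed`.
#'
#' @param corr a `correspondence_set` (>= 4 points, non-collinear in 3D).
#' @param camera a [camera_model()].
#' @param params see [pose_params()].
#' @return a `pose_estimate`: `T` (`rigid_transform`, camera <- object),
#'   `inlier_mask` (logical per correspondence), `rms_reproj_px` (over
#'   inliers), `ambiguous` (planar two-solution flag).
#' @export
estimate_pose <- function(corr, camera, params = pose_params()) {
  stopifnot(inherits(corr, "correspondence_set"))
  p3 <- corr$points3d; p2 <- corr$points2d
  n <- if (is.null(p3)) 0L else nrow(p3)
  st_assert(n >= 4, "DegenerateConfiguration",
            "need at least 4 correspondences, got %d", n)
  svd_d <- svd(sweep(p3, 2, colMeans(p3)))$d
  st_assert(svd_d[2] > 1e-6 * max(svd_d[1], 1), "DegenerateConfiguration",
            "3D points are collinear")
  planar <- svd_d[3] < 1e-6 * max(svd_d[1], 1)
  sample_size <- if (planar) 4L else 6L

  corr <- prepare_corr(corr)
  xy <- pixel_to_normalized(camera, p2)

  best <- NULL; best_inl <- -1L; best_rms <- Inf
  with_seed(params$seed, {
    iters <- params$ransac_iters
    i <- 0L
    while (i < iters) {
      i <- i + 1L
      idx <- sample.int(n, sample_size)
      cands <- pnp_minimal(p3[idx, , drop = FALSE], xy[idx, , drop = FALSE])
      for (cand in cands) {
        e <- reproj_errors(camera, cand, corr)
        inl <- e < params$reproj_threshold_px
        ninl <- sum(inl)
        if (ninl < params$min_inliers) next
        rms <- sqrt(mean(e[inl]^2))
        if (ninl > best_inl || (ninl == best_inl && rms < best_rms)) {
          best <- list(T = cand, inlier = inl)
          best_inl <- ninl; best_rms <- rms
          w <- ninl / n
          if (w > 0) {
            need <- log(1 - params$confidence) /
              log(max(1e-12, 1 - w^sample_size))
            iters <- min(iters, i + ceiling(need))
          }
        }
      }
    }
  })
  st_assert(!is.null(best), "NoConsensus",
            "RANSAC found no model with >= %d inliers", params$min_inliers)

  inl <- best$inlier
  corr_in <- corr_rows(corr, inl)
  refined <- lm_refine(camera, best$T, corr_in, params)

  # one consensus re-evaluation under the refined pose: points marginally
  # misclassified by the (coarser) minimal-solver pose get reconsidered
  inl2 <- reproj_errors(camera, refined, corr) < params$reproj_threshold_px
  if (!identical(inl2, inl) && sum(inl2) >= params$min_inliers) {
    inl <- inl2
    corr_in <- corr_rows(corr, inl)
    refined <- lm_refine(camera, refined, corr_in, params)
  }

  ambiguous <- FALSE
  if (planar) {
    # score both planar solutions on the full inlier set; keep the better,
    # flag the frame if they are nearly indistinguishable (< 5 percent apart)
    cands <- pnp_planar(corr_in$points3d, xy[inl, , drop = FALSE])
    if (length(cands) == 2) {
      refs <- lapply(cands, function(Tc) lm_refine(camera, Tc, corr_in, params))
      r2 <- vapply(refs, function(Tr) {
        sqrt(mean(reproj_errors(camera, Tr, corr_in)^2))
      }, 0)
      if (min(r2) < sqrt(mean(reproj_errors(camera, refined, corr_in)^2))) {
        refined <- refs[[which.min(r2)]]
      }
      ambiguous <- abs(diff(r2)) < 0.05 * max(r2, 1e-12)
    }
  }

  e <- reproj_errors(camera, refined, corr)
  structure(list(T = refined, inlier_mask = inl,
                 rms_reproj_px = sqrt(mean(e[inl]^2)),
                 rms_all_px = sqrt(mean(e^2)),
                 ambiguous = ambiguous, n_points = n),
            class = "pose_estimate")
}

#' Probe pose by the direct PnP method
#'
#' Expresses all marker-corner coordinates in the probe frame (applying
#' `se3_invert(T_probe)` to the cluster-frame corners) before solving, so
#' the estimated pose is directly `T_Cam2Probe`.
#'
#' @param frame an [observation_frame()].
#' @param model a [build_dodecahedron()] model.
#' @param T_probe cluster-to-probe calibration transform
#'   (probe frame <- expressed such that `p_cam = T_cam2dod . T_probe . p_probe`).
#' @param camera a [camera_model()].
#' @param params see [pose_params()].
#' @return a `pose_estimate` whose `T` is `T_Cam2Probe`.
#' @export
pose_direct <- function(frame, model, T_probe, camera, params = pose_params()) {
  st_assert(length(frame$detections) > 0, "DegenerateConfiguration",
            "frame has no detections")
  corr <- build_correspondences(frame, model, se3_invert(T_probe))
  corr <- augment_correspondences(corr)
  estimate_pose(corr, camera, params)
}

#' Probe pose by the concatenation method
#'
#' Estimates the cluster pose `T_Cam2Dod` from cluster-frame corners, then
#' concatenates with the calibration transform:
#' `T_Cam2Probe = T_Cam2Dod . T_probe`.
#'
#' @inheritParams pose_direct
#' @return list with `T_cam2dod` (a `pose_estimate`) and `T_cam2probe`
#'   (a `rigid_transform`).
#' @export
pose_concat <- function(frame, model, T_probe, camera, params = pose_params()) {
  st_assert(length(frame$detections) > 0, "DegenerateConfiguration",
            "frame has no detections")
  corr <- build_correspondences(frame, model)
  corr <- augment_correspondences(corr)
  est <- estimate_pose(corr, camera, params)
  list(T_cam2dod = est, T_cam2probe = se3_compose(est$T, T_probe))
}
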