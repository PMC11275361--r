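#' Time-stamped sequence of rigid transforms
#'
#' @param timestamps numeric, seconds, strictly increasing.
#' @param poses list of `rigid_transform`s, same length.
#' @param rate_hint nominal sampling rate, Hz (informational).
#' @export
pose_stream <- function(timestamps, poses, rate_hint = NA_real_) {
  st_assert(length(timestamps) >= 1 && length(timestamps) == length(poses),
            "BadStream", "timestamps and poses must have equal length >= 1")
  st_assert(all(is.finite(timestamps)) && all(diff(timestamps) > 0),
            "NonMonotoneTimestamps", "timestamps must be strictly increasing")
  st_assert(all(vapply(poses, is_rigid_transform, TRUE)), "BadStream",
            "all poses must be rigid_transform objects")
  structure(list(timestamps = as.numeric(timestamps), poses = poses,
                 rate_hint = rate_hint),
            class = "pose_stream")
}

#' @export
length.pose_stream <- function(x) length(x$timestamps)

#' @export
print.pose_stream <- function(x, ...) {
  cat(sprintf("<pose_stream> %d poses over [%.3f, %.3f] s",
              length(x$timestamps), x$timestamps[1],
              x$timestamps[length(x$timestamps)]),
      if (!is.na(x$rate_hint)) sprintf(" (~%g Hz)", x$rate_hint), "\n", sep = "")
  invisible(x)
}

# n x 3 matrix of translations
stream_translations <- function(stream) {
  t(vapply(stream$poses, function(p) p$t, numeric(3)))
}

#' Savitzky-Golay filtering of stream translations
#'
#' Each translation component is smoothed independently by a local
#' least-squares polynomial (moving window); rotations and timestamps pass
#' through untouched. The filter reproduces polynomials up to `polyorder`
#' exactly, including at the stream edges (where the fit window is
#' off-center).
#'
#' @param stream a [pose_stream()].
#' @param window odd window length, samples.
#' @param polyorder polynomial order, `< window`.
#' @export
savgol_translations <- function(stream, window = 15L, polyorder = 3L) {
  stopifnot(inherits(stream, "pose_stream"))
  n <- length(stream$timestamps)
  st_assert(window %% 2 == 1 && polyorder < window, "WindowTooLarge",
            "window must be odd and greater than polyorder")
  st_assert(window <= n, "WindowTooLarge",
            "window (%d) exceeds stream length (%d)", window, n)
  tr <- stream_translations(stream)
  sm <- apply(tr, 2, function(col) signal::sgolayfilt(col, p = polyorder, n = window))
  poses <- lapply(seq_len(n), function(i) {
    structure(list(R = stream$poses[[i]]$R, t = sm[i, ]),
              class = "rigid_transform")
  })
  pose_stream(stream$timestamps, poses, stream$rate_hint)
}

#' Resample a pose stream at new timestamps
#'
#' Rotation at each target time is the spherical linear interpolation
#' (SLERP) of the bracketing poses' quaternions, hemisphere-aligned first so
#' the shortest arc is taken; translations interpolate linearly per
#' component. Target times must lie inside the source time range
#' (no extrapolation); a target equal to a source timestamp reproduces the
#' source pose exactly.
#'
#' @param stream a [pose_stream()].
#' @param target_times numeric, seconds, strictly increasing.
#' @param rate_hint recorded on the output stream.
#' @export
resample_stream <- function(stream, target_times, rate_hint = NA_real_) {
  stopifnot(inherits(stream, "pose_stream"))
  ts <- stream$timestamps
  st_assert(all(target_times >= ts[1] - 1e-12) &&
              all(target_times <= ts[length(ts)] + 1e-12),
            "OutOfRange", "target times outside [%.6f, %.6f] s", ts[1], ts[length(ts)])
  tr <- stream_translations(stream)
  quats <- t(vapply(stream$poses, function(p) rot_to_quat(p$R), numeric(4)))
  poses <- lapply(target_times, function(tt) {
    i <- findInterval(tt, ts, rightmost.closed = TRUE)
    i <- max(1L, min(i, length(ts) - 1L))
    h <- ts[i + 1] - ts[i]
    a <- (tt - ts[i]) / h
    a <- max(0, min(1, a))
    q <- drop(quat_slerp(quats[i, ], quats[i + 1, ], a))
    structure(list(R = quat_to_rot(q),
                   t = (1 - a) * tr[i, ] + a * tr[i + 1, ]),
              class = "rigid_transform")
  })
  # exact reproduction at source timestamps
  hit <- match(round(target_times, 12), round(ts, 12))
  for (j in which(!is.na(hit))) poses[[j]] <- stream$poses[[hit[j]]]
  pose_stream(target_times, poses, rate_hint)
}

#' Kabsch-Umeyama rigid registration
#'
#' Closed-form SVD solution for the rigid transform (rotation +
#' translation; scale fixed at 1) minimizing
#' `sum ||T . p_i - q_i||^2` over matched point sets. A reflection in the
#' SVD solution is corrected through the sign of the smallest singular
#' value, so the returned rotation is always proper.
#'
#' @param P n x 3 source points (n >= 3, non-collinear), mm.
#' @param Q n x 3 matched target points, mm.
#' @export
kabsch_umeyama <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  st_assert(nrow(P) == nrow(Q) && ncol(P) == 3 && ncol(Q) == 3,
            "ShapeMismatch", "P and Q must be matched n x 3 matrices")
  st_assert(nrow(P) >= 3, "DegenerateConfiguration", "need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  st_assert(svd(Pc)$d[2] > 1e-6 * max(svd(Pc)$d[1], 1),
            "DegenerateConfiguration", "points are collinear")
  H <- crossprod(Pc, Qc)         # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cq - drop(R %*% cp))
}

#' Compose a static world-from-camera pose onto a stream
#'
#' `T_World2Dod(t) = T_World2Cam . T_Cam2Dod(t)` per sample; the camera is
#' static so a single transform is used for all frames. Timestamps are
#' preserved.
#'
#' @param T_world2cam static `rigid_transform`.
#' @param stream a [pose_stream()] of camera-frame poses.
#' @export
reference_chain <- function(T_world2cam, stream) {
  stopifnot(inherits(stream, "pose_stream"))
  pose_stream(stream$timestamps,
              lapply(stream$poses, function(p) se3_compose(T_world2cam, p)),
              stream$rate_hint)
}

#' Ultrasound image geometry
#'
#' @param fov transducer field of view (image width), mm.
#' @param depth useful imaging depth, mm.
#' @param pixel_size mm/px (needed only for pixel-grid mapping).
#' @export
us_image_spec <- function(fov = 38, depth = 30, pixel_size = NA_real_) {
  st_assert(fov >= 0 && depth >= 0, "BadSpec", "fov and depth must be >= 0")
  structure(list(fov = fov, depth = depth, pixel_size = pixel_size),
            class = "us_image_spec")
}

#' Corner points of the US image in the probe frame
#'
#' The probe frame sits at the transducer's geometric center on the probe
#' surface, y-axis along the beam, x-axis along the transducer array,
#' image plane z = 0. Corners are returned in the order
#' `(FOV/2, 0, 0)`, `(FOV/2, d, 0)`, `(-FOV/2, d, 0)`, `(-FOV/2, 0, 0)`.
#'
#' @param spec a [us_image_spec()].
#' @return 4 x 3 matrix, mm.
#' @export
image_corners <- function(spec = us_image_spec()) {
  stopifnot(inherits(spec, "us_image_spec"))
  rbind(c(spec$fov / 2, 0, 0),
        c(spec$fov / 2, spec$depth, 0),
        c(-spec$fov / 2, spec$depth, 0),
        c(-spec$fov / 2, 0, 0))
}

#' Map US image corners through a pose stream
#'
#' For each frame, places the four image corners (probe frame) into the
#' camera frame:
#' \describe{
#'   \item{ref}{`T_Cam2Dod_IR . T_probe` applied to the corners (reference
#'     tracking chain).}
#'   \item{direct}{`T_Cam2Probe` applied directly (direct PnP method).}
#'   \item{concat}{`T_Cam2Dod_RGB . T_probe` applied (concatenation
#'     method).}
#'   \item{origin}{the pose's translation vector only — one point per
#'     frame, the rotational component is discarded.}
#' }
#'
#' @param method one of `"ref"`, `"direct"`, `"concat"`, `"origin"`.
#' @param stream a [pose_stream()]: cluster poses for `ref`/`concat`/
#'   `origin`, probe poses for `direct`.
#' @param T_probe probe calibration transform (ignored for `direct` and
#'   `origin`).
#' @param spec a [us_image_spec()].
#' @return list of per-frame corner matrices (4 x 3 mm; 1 x 3 for
#'   `origin`), with the stream timestamps as attribute `"timestamps"`.
#' @export
map_corners <- function(method = c("ref", "direct", "concat", "origin"),
                        stream, T_probe = se3_identity(),
                        spec = us_image_spec()) {
  method <- match.arg(method)
  stopifnot(inherits(stream, "pose_stream"))
  corners <- image_corners(spec)
  out <- lapply(stream$poses, function(p) {
    switch(method,
           ref = ,
           concat = se3_apply(se3_compose(p, T_probe), corners),
           direct = se3_apply(p, corners),
           origin = matrix(p$t, 1, 3))
  })
  attr(out, "timestamps") <- stream$timestamps
  out
}

#' Error statistics between candidate and reference corner trajectories
#'
#' Stacks the signed per-corner error vectors
#' `e = p_candidate - p_reference` over all frames and reports the per-axis
#' mean and population standard deviation (`1/N` convention, matching the
#' definition sigma = sqrt((1/N) sum (e - mean)^2)), plus the Euclidean
#' norms of the mean and standard-deviation 3-vectors — the layout of the
#' evaluation table.
#'
#' @param candidate,reference lists of matched corner matrices (as returned
#'   by [map_corners()]) or plain n x 3 matrices.
#' @return an `error_stats` list: `n`, `mean` (3-vector mm), `std`
#'   (3-vector mm), `mean_norm`, `std_norm`.
#' @export
error_stats <- function(candidate, reference) {
  cand <- if (is.list(candidate)) do.call(rbind, candidate) else rbind(candidate)
  ref <- if (is.list(reference)) do.call(rbind, reference) else rbind(reference)
  st_assert(all(dim(cand) == dim(ref)) && ncol(cand) == 3 && nrow(cand) >= 1,
            "ShapeMismatch", "candidate and reference must be matched n x 3 point sets")
  e <- cand - ref
  n <- nrow(e)
  mu <- colMeans(e)
  sdv <- sqrt(colMeans(sweep(e, 2, mu)^2))   # population (1/N) convention
  structure(list(n = n, mean = mu, std = sdv,
                 mean_norm = vnorm(mu), std_norm = vnorm(sdv)),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("<error_stats> N = %d corner points\n", x$n))
  m <- rbind(c(x$mean, x$mean_norm), c(x$std, x$std_norm))
  dimnames(m) <- list(c("mean [mm]", "std  [mm]"), c("x", "y", "z", "norm"))
  print(round(m, 3))
  invisible(x)
}

#' Map all US image pixels of a frame into 3D
#'
#' Assigns each pixel center `(r, c)` of an `rows x cols` B-mode image its
#' probe-frame position `(FOV/2 - c * pixel_size, r * pixel_size, 0)` and
#' pushes it through the tracking chain `T_pose . T_probe`, yielding the
#' planar point set that volume compounding would consume.
#'
#' @param pose the frame's cluster pose (`rigid_transform`).
#' @param T_probe probe calibration transform.
#' @param spec a [us_image_spec()] with `pixel_size` set.
#' @param rows,cols image size in pixels.
#' @return `(rows * cols)` x 3 matrix of camera-frame points, mm
#'   (row-major: pixel (0,0), (0,1), ...).
#' @export
map_image_pixels <- function(pose, T_probe, spec, rows, cols) {
  st_assert(is.finite(spec$pixel_size) && spec$pixel_size > 0, "BadSpec",
            "spec$pixel_size must be set")
  grid <- expand.grid(c = seq_len(cols) - 1, r = seq_len(rows) - 1)
  grid <- grid[order(grid$r, grid$c), ]
  pts <- cbind(spec$fov / 2 - grid$c * spec$pixel_size,
               grid$r * spec$pixel_size,
               0)
  se3_apply(se3_compose(pose, T_probe), pts)
}
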