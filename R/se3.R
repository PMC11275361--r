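#' Rigid transforms in SE(3)
#'
#' A `rigid_transform` stores a rotation matrix `R` (3x3, orthonormal,
#' det = +1) and a translation vector `t` (length 3, millimetres) and maps
#' points `u` to `R %*% u + t`. The pair is kept separate rather than as a
#' 4x4 homogeneous matrix so that the rotation invariants can be validated
#' on construction; the 4x4 form exists only for serialization
#' ([as_matrix4()]).
#'
#' @param R 3x3 rotation matrix (unitless).
#' @param t translation, numeric length 3 (mm).
#' @param tol orthonormality tolerance for validation; inputs that have been
#'   through file round-trips may carry up to ~1e-6 of drift.
#' @return object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' T1 <- rigid_transform(rot_z(pi / 6), c(1, 2, 3))
#' se3_apply(T1, c(0, 0, 0))   # == t
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0), tol = 1e-6) {
  R <- unname(as.matrix(R)); t <- unname(as.numeric(t))
  st_assert(all(is.finite(R)) && all(is.finite(t)) &&
              identical(dim(R), c(3L, 3L)) && length(t) == 3,
            "NotARotation", "R must be a finite 3x3 matrix and t a finite 3-vector")
  ortho <- max(abs(crossprod(R) - diag(3)))
  st_assert(ortho <= tol, "NotARotation",
            "R is not orthonormal (max |R'R - I| = %.3g > %.3g)", ortho, tol)
  st_assert(det(R) > 0, "NotARotation", "R is a reflection (det(R) = %.6f)", det(R))
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  m <- cbind(x$R, x$t)
  dimnames(m) <- list(c("x", "y", "z"), c("R.1", "R.2", "R.3", "t[mm]"))
  print(round(m, 6))
  invisible(x)
}

#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Identity transform
#' @export
se3_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Compose two rigid transforms
#'
#' Equals the 4x4 homogeneous matrix product `A %*% B`: the result applies
#' `B` first, then `A`.
#' @param A,B `rigid_transform` objects.
#' @export
se3_compose <- function(A, B) {
  stopifnot(is_rigid_transform(A), is_rigid_transform(B))
  structure(list(R = A$R %*% B$R, t = drop(A$R %*% B$t) + A$t),
            class = "rigid_transform")
}

#' Invert a rigid transform
#'
#' Returns `(R', t') = (t(R), -t(R) %*% t)` so that
#' `se3_compose(T, se3_invert(T))` is the identity.
#' @param T a `rigid_transform`.
#' @export
se3_invert <- function(T) {
  stopifnot(is_rigid_transform(T))
  Rt <- t(T$R)
  structure(list(R = Rt, t = drop(-Rt %*% T$t)), class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param T a `rigid_transform`.
#' @param pts numeric length-3 vector or an n x 3 matrix of points (mm).
#' @return same shape as `pts`. The mapping is an isometry: pairwise
#'   distances and handedness are preserved.
#' @export
se3_apply <- function(T, pts) {
  stopifnot(is_rigid_transform(T))
  if (is.null(dim(pts))) {
    st_assert(length(pts) == 3 && all(is.finite(pts)), "BadPoint",
              "point must be a finite 3-vector")
    return(drop(T$R %*% pts) + T$t)
  }
  pts <- as.matrix(pts)
  st_assert(ncol(pts) == 3 && all(is.finite(pts)), "BadPoint",
            "points must be an n x 3 finite matrix")
  sweep(pts %*% t(T$R), 2, T$t, "+")
}

#' 4x4 homogeneous matrix form (serialization only)
#' @param T a `rigid_transform`.
#' @export
as_matrix4 <- function(T) {
  stopifnot(is_rigid_transform(T))
  rbind(cbind(T$R, T$t), c(0, 0, 0, 1))
}

#' Build a rigid transform from a 4x4 homogeneous matrix
#' @param M 4x4 matrix with last row (0,0,0,1).
#' @inheritParams rigid_transform
#' @export
from_matrix4 <- function(M, tol = 1e-6) {
  M <- as.matrix(M)
  st_assert(identical(dim(M), c(4L, 4L)) &&
              max(abs(M[4, ] - c(0, 0, 0, 1))) < 1e-9,
            "NotARotation", "M must be 4x4 homogeneous with last row (0,0,0,1)")
  rigid_transform(M[1:3, 1:3], M[1:3, 4], tol = tol)
}

#' Elementary rotations (radians)
#' @param theta angle in radians.
#' @name elementary_rotations
#' @export
rot_x <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}
#' @rdname elementary_rotations
#' @export
rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}
#' @rdname elementary_rotations
#' @export
rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' Axis-angle (rotation vector) to rotation matrix
#'
#' Rodrigues formula; `rvec` has magnitude = angle (radians), direction =
#' axis. Used as the minimal rotation parameterization in the
#' Levenberg-Marquardt refinement.
#' @param rvec numeric length 3.
#' @export
rotvec_to_rot <- function(rvec) {
  th <- sqrt(sum(rvec^2))
  if (th < 1e-12) {
    K <- skew3(rvec)
    return(diag(3) + K + 0.5 * (K %*% K))  # 2nd-order small-angle series
  }
  k <- rvec / th
  K <- skew3(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation matrix to axis-angle vector (angle in [0, pi])
#' @param R 3x3 rotation matrix.
#' @export
rot_to_rotvec <- function(R) {
  q <- rot_to_quat(R)
  # q = (cos(th/2), sin(th/2) * axis); w >= 0 so th in [0, pi]
  v <- q[2:4]
  s <- sqrt(sum(v^2))
  if (s < 1e-12) return(c(0, 0, 0))
  th <- 2 * atan2(s, q[1])
  v / s * th
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Rotation matrix <-> unit quaternion conversion
#'
#' Quaternions are stored in `(w, x, y, z)` order and hemisphere-normalized
#' on output: `w >= 0`, and if `w == 0` the first nonzero component is
#' positive, so serialization is deterministic.
#'
#' @param R 3x3 rotation matrix.
#' @return `rot_to_quat`: numeric length 4 `(w, x, y, z)` with unit norm.
#' @export
rot_to_quat <- function(R) {
  # Shepperd's method: pick the largest of the four squared components.
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr >= R[1, 1] && tr >= R[2, 2] && tr >= R[3, 3]) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_hemisphere(q / sqrt(sum(q^2)))
}

#' @rdname rot_to_quat
#' @param q numeric length 4 quaternion `(w, x, y, z)`; renormalized before
#'   conversion.
#' @export
quat_to_rot <- function(q) {
  st_assert(length(q) == 4 && all(is.finite(q)) && sum(q^2) > 0,
            "BadQuaternion", "q must be a finite nonzero 4-vector (w,x,y,z)")
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Canonical hemisphere for a quaternion
#'
#' Flips the sign so that `w >= 0`; if `w == 0`, the first nonzero component
#' is made positive. `q` and `-q` encode the same rotation.
#' @param q numeric length 4.
#' @export
quat_hemisphere <- function(q) {
  nz <- which(abs(q) > 1e-15)
  if (length(nz) && q[nz[1]] < 0) q <- -q
  q
}

#' Spherical linear interpolation between unit quaternions
#'
#' Interpolates along the shortest great-circle arc; `q1` is negated first
#' if `sum(q0 * q1) < 0` (hemisphere alignment), so the path never takes the
#' long way round.
#' @param q0,q1 unit quaternions `(w, x, y, z)`.
#' @param alpha interpolation fraction in `[0, 1]` (vectorized).
#' @return matrix `length(alpha)` x 4 of unit quaternions.
#' @export
quat_slerp <- function(q0, q1, alpha) {
  q0 <- q0 / sqrt(sum(q0^2)); q1 <- q1 / sqrt(sum(q1^2))
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  if (d > 1 - 1e-12) {
    # nearly parallel: nlerp is numerically safer and equal to slerp here
    out <- outer(1 - alpha, q0) + outer(alpha, q1)
    return(out / sqrt(rowSums(out^2)))
  }
  th <- acos(min(d, 1))
  s <- sin(th)
  outer(sin((1 - alpha) * th) / s, q0) + outer(sin(alpha * th) / s, q1)
}
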