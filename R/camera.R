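#' Pinhole camera model with Brown-Conrady distortion
#'
#' Camera frame convention: x right, y down, z forward (optical axis); pixel
#' origin at the top-left pixel center, matching mainstream computer-vision
#' conventions so that observations from a real marker detector drop in
#' unchanged.
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels, inside the image.
#' @param dist radial/tangential distortion coefficients
#'   `(k1, k2, p1, p2, k3)`; defaults to zero (factory-calibrated cameras
#'   usually ship with small coefficients).
#' @param width,height image size in pixels.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(fx, fy, cx, cy, dist = c(0, 0, 0, 0, 0),
                         width = 640L, height = 480L) {
  st_assert(fx > 0 && fy > 0, "BadCamera", "fx and fy must be positive")
  st_assert(cx >= 0 && cx < width && cy >= 0 && cy < height, "BadCamera",
            "principal point must lie inside the image")
  st_assert(length(dist) == 5, "BadCamera",
            "dist must have 5 coefficients (k1,k2,p1,p2,k3)")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 dist = as.numeric(dist),
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_model")
}

# Apply Brown-Conrady distortion to normalized image coordinates (n x 2).
distort_normalized <- function(camera, xy) {
  d <- camera$dist
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
  xd <- x * radial + 2 * d[3] * x * y + d[4] * (r2 + 2 * x^2)
  yd <- y * radial + d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y
  cbind(xd, yd)
}

# Invert the distortion by fixed-point iteration (exact for zero distortion).
undistort_normalized <- function(camera, xy, iters = 20L) {
  if (all(camera$dist == 0)) return(xy)
  u <- xy
  for (i in seq_len(iters)) {
    e <- distort_normalized(camera, u) - xy
    u <- u - e
  }
  u
}

# Pixel coordinates -> undistorted normalized coordinates.
pixel_to_normalized <- function(camera, px) {
  px <- rbind(px)  # tolerate a single point given as a vector
  xy <- cbind((px[, 1] - camera$cx) / camera$fx,
              (px[, 2] - camera$cy) / camera$fy)
  undistort_normalized(camera, xy)
}

#' Project 3D points to pixel coordinates
#'
#' Points given in the object frame are first mapped to the camera frame by
#' `T_cam_from_obj`, then projected through the pinhole with Brown-Conrady
#' distortion: `u = fx * distort(x/z) + cx`, `v = fy * distort(y/z) + cy`.
#'
#' @param camera a [camera_model()].
#' @param T_cam_from_obj `rigid_transform` mapping object-frame points into
#'   the camera frame (identity if `pts` are already camera-frame).
#' @param pts n x 3 matrix (or length-3 vector) of points, mm.
#' @return n x 2 matrix of pixel coordinates.
#' @export
project_points <- function(camera, T_cam_from_obj = se3_identity(), pts) {
  stopifnot(inherits(camera, "camera_model"))
  pts <- rbind(pts)
  pc <- se3_apply(T_cam_from_obj, pts)
  pc <- rbind(pc)
  st_assert(all(pc[, 3] > 0), "BehindCamera",
            "all points must have positive camera-frame z")
  xy <- distort_normalized(camera, pc[, 1:2, drop = FALSE] / pc[, 3])
  cbind(camera$fx * xy[, 1] + camera$cx, camera$fy * xy[, 2] + camera$cy)
}

#' Read / write camera intrinsics JSON
#'
#' Schema: `{fx, fy, cx, cy, dist:[k1,k2,p1,p2,k3], width, height}`.
#' @param path file path.
#' @export
read_camera_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_model(j$fx, j$fy, j$cx, j$cy, j$dist, j$width, j$height)
}

#' @rdname read_camera_json
#' @param camera a [camera_model()].
#' @export
write_camera_json <- function(camera, path) {
  jsonlite::write_json(unclass(camera), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
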