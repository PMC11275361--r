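# Shared fixtures, built in code at test time.

fix_camera <- function() camera_model(600, 600, 320, 240, width = 640, height = 480)

# one cached cluster model for the whole suite (construction is deterministic)
fix_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_dodecahedron()
    cache
  }
})

# random proper rotation from a normalized quaternion draw
random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_rot(q / sqrt(sum(q^2)))
}

random_transform <- function(t_scale = 100) {
  rigid_transform(random_rotation(), stats::rnorm(3, 0, t_scale))
}

# noiseless observation frame of all self-occlusion-visible markers
noiseless_frame <- function(T_pose, camera = fix_camera(), model = fix_model(),
                            timestamp = 0) {
  ids <- visible_markers(camera, T_pose, model)
  dets <- lapply(ids, function(id) {
    list(id = id,
         corners = project_points(camera, T_pose, marker_corners_local(model, id)))
  })
  observation_frame(timestamp, dets)
}

rot_angle_between <- function(R1, R2) {
  sqrt(sum(rot_to_rotvec(t(R1) %*% R2)^2))
}
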