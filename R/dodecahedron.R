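#' Regular-dodecahedron fiducial marker cluster
#'
#' Builds the geometry of a regular dodecahedron carrying one square fiducial
#' (ArUco-style) marker per face. The cluster frame has its origin at the
#' solid's centroid. Vertices come from the canonical
#' `(+/-1, +/-1, +/-1)` / golden-ratio construction, scaled to the requested
#' edge length and enumerated deterministically (lexicographic vertex sort;
#' faces sorted by their outward-normal direction), so identical inputs give
#' bit-identical corner tables.
#'
#' Each marker square lies in its face plane with its lower side parallel to
#' the face's canonical edge at perpendicular distance `marker_inset` from
#' it, centered on that edge's perpendicular bisector. The canonical edge of
#' a face is the one whose (sorted) global vertex-index pair is
#' lexicographically smallest.
#'
#' @param edge_length dodecahedron edge, mm. Default 31: the smallest round
#'   value for which a 25 mm marker with a 2.5 mm inset fits the pentagonal
#'   face (checked geometrically for any inputs).
#' @param marker_size side of the square marker, mm.
#' @param marker_inset perpendicular distance from the marker's lower side
#'   to the face edge, mm.
#' @param id_assignment integer vector of 12 distinct marker ids, assigned
#'   to faces in enumeration order. Default `0:11`.
#' @return object of class `dodecahedron_model`: fields `edge_length`,
#'   `marker_size`, `marker_inset`, `vertices` (20 x 3), and `faces`, a list
#'   of 12 entries each with `marker_id`, `center`, `outward_normal`,
#'   `vertex_idx` (5, ordered around the face), and `corners_local`
#'   (4 x 3 marker corners, mm, cluster frame, ordered top-left, top-right,
#'   bottom-right, bottom-left in the marker's own frame).
#' @export
build_dodecahedron <- function(edge_length = 31, marker_size = 25,
                               marker_inset = 2.5, id_assignment = 0:11) {
  st_assert(edge_length > 0 && marker_size > 0 && marker_inset >= 0,
            "BadGeometry", "edge_length, marker_size > 0 and marker_inset >= 0 required")
  st_assert(length(id_assignment) == 12 && !anyDuplicated(id_assignment),
            "BadGeometry", "id_assignment must be 12 distinct integers")
  phi <- (1 + sqrt(5)) / 2
  s <- edge_length / (2 / phi)  # canonical construction has edge 2/phi

  V <- rbind(
    as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
    cbind(0, c(-1, -1, 1, 1) / phi, c(-1, 1, -1, 1) * phi),
    cbind(c(-1, -1, 1, 1) / phi, c(-1, 1, -1, 1) * phi, 0),
    cbind(c(-1, 1, -1, 1) * phi, 0, c(-1, -1, 1, 1) / phi))
  V <- V[order(V[, 1], V[, 2], V[, 3]), , drop = FALSE] * s
  dimnames(V) <- NULL

  # 12 face-center directions of this construction: cyclic perms of (1,0,phi)
  N <- rbind(cbind(c(-1, -1, 1, 1), 0, c(-1, 1, -1, 1) * phi),
             cbind(0, c(-1, 1, -1, 1) * phi, c(-1, -1, 1, 1)),
             cbind(c(-1, 1, -1, 1) * phi, c(-1, -1, 1, 1), 0))
  N <- N / sqrt(rowSums(N^2))
  N <- N[order(N[, 1], N[, 2], N[, 3]), , drop = FALSE]

  faces <- lapply(seq_len(12), function(f) {
    n <- N[f, ]
    proj <- drop(V %*% n)
    idx <- order(proj, decreasing = TRUE)[1:5]      # the 5 extreme vertices
    ctr <- colMeans(V[idx, , drop = FALSE])
    # order counter-clockwise about the outward normal, starting at the
    # lowest-index vertex for determinism
    e1 <- V[idx[1], ] - ctr; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(n, e1)
    rel <- sweep(V[idx, , drop = FALSE], 2, ctr)
    ang <- atan2(rel %*% e2, rel %*% e1)
    idx <- idx[order(ang)]
    start <- which.min(idx)
    idx <- idx[((seq_len(5) + start - 2) %% 5) + 1]

    # canonical edge: cyclically-adjacent pair with smallest sorted indices
    pairs <- cbind(idx, idx[c(2:5, 1)])
    keys <- apply(pairs, 1, function(p) sort(p))
    best <- order(keys[1, ], keys[2, ])[1]
    a <- min(pairs[best, ]); b <- max(pairs[best, ])

    e_hat <- V[b, ] - V[a, ]; e_hat <- e_hat / sqrt(sum(e_hat^2))
    mid <- (V[a, ] + V[b, ]) / 2
    y_hat <- ctr - mid; y_hat <- y_hat / sqrt(sum(y_hat^2))  # edge -> interior

    mc <- mid + y_hat * (marker_inset + marker_size / 2)
    h <- marker_size / 2
    corners <- rbind(mc - h * e_hat + h * y_hat,   # top-left
                     mc + h * e_hat + h * y_hat,   # top-right
                     mc + h * e_hat - h * y_hat,   # bottom-right
                     mc - h * e_hat - h * y_hat)   # bottom-left

    list(marker_id = id_assignment[f], center = ctr, outward_normal = n,
         vertex_idx = idx, corners_local = corners)
  })

  model <- structure(list(edge_length = edge_length, marker_size = marker_size,
                          marker_inset = marker_inset, vertices = V,
                          faces = faces),
                     class = "dodecahedron_model")
  check_marker_fit(model)
  model
}

# Every marker corner must lie strictly inside its pentagonal face.
check_marker_fit <- function(model) {
  for (face in model$faces) {
    P <- model$vertices[face$vertex_idx, , drop = FALSE]
    n <- face$outward_normal
    for (k in seq_len(5)) {
      a <- P[k, ]; b <- P[(k %% 5) + 1, ]
      inward <- cross3(n, b - a)              # CCW ordering: points inside
      for (j in seq_len(4)) {
        if (sum((face$corners_local[j, ] - a) * inward) <= 0) {
          st_stop("MarkerDoesNotFit",
                  "a %g mm marker with %g mm inset does not fit a pentagon of edge %g mm",
                  model$marker_size, model$marker_inset, model$edge_length)
        }
      }
    }
  }
  invisible(TRUE)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dodecahedron inradius (center-to-face-plane distance)
#' @param edge_length edge, mm.
#' @export
dodecahedron_inradius <- function(edge_length) {
  edge_length / 2 * sqrt((25 + 11 * sqrt(5)) / 10)
}

#' Marker corner coordinates in the cluster frame
#'
#' @param model a [build_dodecahedron()] model.
#' @param marker_id integer id present in the model.
#' @return 4 x 3 matrix, corners ordered top-left, top-right, bottom-right,
#'   bottom-left in the marker's own frame (the simulator and any detector
#'   adapter use the same convention).
#' @export
marker_corners_local <- function(model, marker_id) {
  stopifnot(inherits(model, "dodecahedron_model"))
  for (face in model$faces) {
    if (face$marker_id == marker_id) return(face$corners_local)
  }
  st_stop("UnknownMarkerId", "marker id %s not present in the cluster", marker_id)
}

#' Self-occlusion-aware marker visibility
#'
#' A marker is visible iff (a) its face is front-facing — the outward normal
#' `n` and face center `c`, both in camera coordinates, satisfy
#' `dot(n, c) < 0` — and (b) all four projected marker corners fall inside
#' the image bounds. Convexity of the dodecahedron means a finite viewpoint
#' can front-face at most 6 of the 12 faces.
#'
#' @param camera a [camera_model()].
#' @param T_cam_from_dod cluster pose (camera <- cluster frame).
#' @param model a [build_dodecahedron()] model.
#' @return integer vector of visible marker ids (possibly empty).
#' @export
visible_markers <- function(camera, T_cam_from_dod, model) {
  stopifnot(inherits(model, "dodecahedron_model"))
  ctr_cam <- se3_apply(T_cam_from_dod, c(0, 0, 0))
  st_assert(ctr_cam[3] > 0, "BehindCamera", "cluster centroid is behind the camera")
  ids <- integer(0)
  for (face in model$faces) {
    n_cam <- drop(T_cam_from_dod$R %*% face$outward_normal)
    c_cam <- se3_apply(T_cam_from_dod, face$center)
    if (sum(n_cam * c_cam) >= 0) next            # back-facing
    cc <- se3_apply(T_cam_from_dod, face$corners_local)
    if (any(cc[, 3] <= 0)) next
    px <- project_points(camera, se3_identity(), cc)
    inside <- px[, 1] >= 0 & px[, 1] <= camera$width - 1 &
      px[, 2] >= 0 & px[, 2] <= camera$height - 1
    if (all(inside)) ids <- c(ids, face$marker_id)
  }
  ids
}

#' Read / write cluster geometry JSON (the "marker map")
#'
#' Schema:
#' `{edge_length, marker_size, marker_inset,
#'   faces:[{marker_id, corners_local:[[x,y,z] x 4]}]}`.
#' Reading reconstructs the model from the stored parameters and verifies the
#' stored corner tables match the rebuilt geometry.
#' @param path file path.
#' @export
read_cluster_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- vapply(seq_len(nrow(j$faces)), function(i) j$faces$marker_id[i], 0)
  model <- build_dodecahedron(j$edge_length, j$marker_size, j$marker_inset,
                              as.integer(ids))
  for (i in seq_along(model$faces)) {
    stored <- j$faces$corners_local[[i]]
    stored <- if (is.list(stored)) do.call(rbind, lapply(stored, unlist)) else as.matrix(stored)
    st_assert(max(abs(stored - model$faces[[i]]$corners_local)) < 1e-6,
              "BadGeometry", "stored corner table disagrees with rebuilt geometry")
  }
  model
}

#' @rdname read_cluster_json
#' @param model a `dodecahedron_model`.
#' @export
write_cluster_json <- function(model, path) {
  faces <- lapply(model$faces, function(f) {
    list(marker_id = f$marker_id,
         corners_local = lapply(seq_len(4), function(i) f$corners_local[i, ]))
  })
  jsonlite::write_json(list(edge_length = model$edge_length,
                            marker_size = model$marker_size,
                            marker_inset = model$marker_inset,
                            faces = faces),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Infrared reference marker cluster
#'
#' Models the small cluster of retroreflective markers press-fitted to the
#' probe fixture and tracked by the stereophotogrammetric reference system.
#' Default geometry: 4 markers at tetrahedral positions, 40 mm circumradius.
#'
#' @param points_local n x 3 matrix (n >= 3) of marker positions in the
#'   cluster frame, mm; must not be collinear.
#' @param labels optional character labels.
#' @export
ir_cluster_model <- function(points_local = NULL, labels = NULL) {
  if (is.null(points_local)) {
    points_local <- 40 / sqrt(3) * rbind(c(1, 1, 1), c(1, -1, -1),
                                         c(-1, 1, -1), c(-1, -1, 1))
  }
  points_local <- as.matrix(points_local)
  st_assert(nrow(points_local) >= 3 && ncol(points_local) == 3,
            "BadGeometry", "need at least 3 IR markers (n x 3 matrix)")
  ctr <- sweep(points_local, 2, colMeans(points_local))
  sv <- svd(ctr)$d
  st_assert(sv[2] > 1e-6, "BadGeometry", "IR markers must not be collinear")
  if (is.null(labels)) labels <- paste0("m", seq_len(nrow(points_local)))
  structure(list(points_local = points_local, labels = labels),
            class = "ir_cluster_model")
}
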