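#' Track a sequence of observation frames
#'
#' Runs per-frame pose estimation over a list of frames. Frames where
#' estimation fails (no detections, degenerate geometry, no RANSAC
#' consensus) are carried as gaps: they are simply absent from the output
#' stream, and downstream filtering/resampling never sees them.
#'
#' @param frames list of [observation_frame()]s.
#' @param model a [build_dodecahedron()] model.
#' @param T_probe probe calibration transform.
#' @param camera a [camera_model()].
#' @param params see [pose_params()].
#' @param method `"direct"` (solve in the probe frame) or `"concat"`
#'   (solve the cluster pose, then concatenate with `T_probe`).
#' @return list: `stream` (a [pose_stream()] of `T_Cam2Probe`),
#'   `cluster_stream` (`T_Cam2Dod`, concat method only), `n_failed`,
#'   `failed_idx`, `ambiguous_idx`.
#' @export
track_frames <- function(frames, model, T_probe, camera,
                         params = pose_params(),
                         method = c("direct", "concat")) {
  method <- match.arg(method)
  ts <- c(); poses <- list(); cluster_poses <- list()
  failed <- integer(0); ambiguous <- integer(0)
  for (i in seq_along(frames)) {
    res <- tryCatch({
      if (method == "direct") {
        est <- pose_direct(frames[[i]], model, T_probe, camera, params)
        list(probe = est$T, cluster = NULL, amb = est$ambiguous)
      } else {
        pc <- pose_concat(frames[[i]], model, T_probe, camera, params)
        list(probe = pc$T_cam2probe, cluster = pc$T_cam2dod$T,
             amb = pc$T_cam2dod$ambiguous)
      }
    }, sonotrackError = function(e) NULL)
    if (is.null(res)) {
      failed <- c(failed, i)
      next
    }
    if (isTRUE(res$amb)) ambiguous <- c(ambiguous, i)
    ts <- c(ts, frames[[i]]$timestamp)
    poses <- c(poses, list(res$probe))
    if (!is.null(res$cluster)) cluster_poses <- c(cluster_poses, list(res$cluster))
  }
  st_assert(length(ts) >= 1, "NoConsensus", "pose estimation failed on every frame")
  list(stream = pose_stream(ts, poses),
       cluster_stream = if (length(cluster_poses)) pose_stream(ts, cluster_poses) else NULL,
       n_failed = length(failed), failed_idx = failed,
       ambiguous_idx = ambiguous)
}

#' Assemble a pipeline configuration
#'
#' In-memory configuration for [run_pipeline()]; [read_pipeline_yaml()]
#' builds one from a YAML file referencing the on-disk formats.
#'
#' @param frames list of [observation_frame()]s.
#' @param camera a [camera_model()].
#' @param model a [build_dodecahedron()] model.
#' @param calibration a `probe_calibration` (from [calibrate()] or
#'   [read_calibration_json()]).
#' @param ir an `ir_stream` (reference system recording).
#' @param ir_cluster the [ir_cluster_model()] behind the IR stream.
#' @param T_world2cam static world-from-camera pose.
#' @param method `"direct"`, `"concat"` or `"both"`.
#' @param params see [pose_params()].
#' @param filter_window,filter_polyorder Savitzky-Golay settings for the
#'   translation filter; the window is clamped to the stream length when a
#'   short recording cannot fill it.
#' @param spec a [us_image_spec()].
#' @param include_origin also evaluate the translation-only
#'   (rotation-ignored) cluster-origin error row.
#' @export
pipeline_config <- function(frames, camera, model, calibration, ir,
                            ir_cluster, T_world2cam,
                            method = c("both", "direct", "concat"),
                            params = pose_params(),
                            filter_window = 15L, filter_polyorder = 3L,
                            spec = us_image_spec(), include_origin = TRUE) {
  method <- match.arg(method)
  structure(list(frames = frames, camera = camera, model = model,
                 calibration = calibration, ir = ir, ir_cluster = ir_cluster,
                 T_world2cam = T_world2cam, method = method, params = params,
                 filter_window = as.integer(filter_window),
                 filter_polyorder = as.integer(filter_polyorder),
                 spec = spec, include_origin = isTRUE(include_origin)),
            class = "pipeline_config")
}

clamp_window <- function(window, polyorder, n) {
  w <- min(window, if (n %% 2 == 1) n else n - 1)
  if (w < polyorder + 1) w <- if ((polyorder + 1) %% 2 == 1) polyorder + 1 else polyorder + 2
  if (w %% 2 == 0) w <- w - 1
  max(w, 1)
}

#' Run the full tracking-evaluation pipeline
#'
#' Stages: per-frame pose estimation (direct and/or concatenation method),
#' Savitzky-Golay filtering of the candidate translations, reference
#' reconstruction from the IR stream (per-sample rigid registration, then
#' SLERP/linear resampling of the 200 Hz reference onto the candidate's
#' frame timestamps — never the reverse), image-corner mapping through each
#' chain, and error statistics. Emits a report with one row per method in
#' the layout of the evaluation table (per-axis mean error, its norm,
#' per-axis standard deviation, its norm), plus per-stage timings and
#' frame-drop counts.
#'
#' @param config a [pipeline_config()].
#' @return a `tracking_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  methods <- if (config$method == "both") c("direct", "concat") else config$method
  T_probe <- config$calibration$T_probe
  timing <- c(); t0 <- Sys.time()
  stage <- function(name) {
    t1 <- Sys.time()
    timing[[name]] <<- as.numeric(t1 - t0, units = "secs")
    t0 <<- t1
  }

  tracks <- lapply(methods, function(m) {
    track_frames(config$frames, config$model, T_probe, config$camera,
                 config$params, method = m)
  })
  names(tracks) <- methods
  stage("track")

  filtered <- lapply(tracks, function(tr) {
    w <- clamp_window(config$filter_window, config$filter_polyorder,
                      length(tr$stream$timestamps))
    out <- tr
    out$stream <- savgol_translations(tr$stream, w, config$filter_polyorder)
    if (!is.null(tr$cluster_stream)) {
      out$cluster_stream <- savgol_translations(tr$cluster_stream, w,
                                                config$filter_polyorder)
    }
    out
  })
  stage("filter")

  ref200 <- ir_to_pose_stream(config$ir, config$ir_cluster, config$T_world2cam)
  stage("reference")

  rows <- list()
  for (m in methods) {
    cand <- filtered[[m]]$stream
    keep <- cand$timestamps >= ref200$timestamps[1] &
      cand$timestamps <= ref200$timestamps[length(ref200$timestamps)]
    cand <- pose_stream(cand$timestamps[keep], cand$poses[keep])
    ref <- resample_stream(ref200, cand$timestamps)
    corners_ref <- map_corners("ref", ref, T_probe, config$spec)
    corners_cand <- if (m == "direct") {
      map_corners("direct", cand, spec = config$spec)
    } else {
      cl <- filtered[[m]]$cluster_stream
      cl <- pose_stream(cl$timestamps[keep], cl$poses[keep])
      map_corners("concat", cl, T_probe, config$spec)
    }
    rows[[m]] <- error_stats(corners_cand, corners_ref)
    if (config$include_origin && m == "concat") {
      cl <- filtered[[m]]$cluster_stream
      cl <- pose_stream(cl$timestamps[keep], cl$poses[keep])
      rows[["origin"]] <- error_stats(map_corners("origin", cl, spec = config$spec),
                                      map_corners("origin", ref, spec = config$spec))
    }
  }
  stage("evaluate")

  structure(list(rows = rows,
                 n_frames = length(config$frames),
                 n_failed = vapply(tracks, function(tr) tr$n_failed, 0L),
                 n_ambiguous = vapply(tracks, function(tr) length(tr$ambiguous_idx), 0L),
                 stage_seconds = unlist(timing)),
            class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat("<tracking_report>\n")
  tab <- do.call(rbind, lapply(names(x$rows), function(m) {
    s <- x$rows[[m]]
    data.frame(method = m,
               mean_x = s$mean[1], mean_y = s$mean[2], mean_z = s$mean[3],
               mean_norm = s$mean_norm,
               std_x = s$std[1], std_y = s$std[2], std_z = s$std[3],
               std_norm = s$std_norm)
  }))
  tab[-1] <- round(tab[-1], 3)
  print(tab, row.names = FALSE)
  cat(sprintf("frames: %d; failed: %s; ambiguous: %s\n", x$n_frames,
              paste(x$n_failed, collapse = "/"),
              paste(x$n_ambiguous, collapse = "/")))
  cat("stage seconds:",
      paste(sprintf("%s=%.2f", names(x$stage_seconds), x$stage_seconds),
            collapse = " "), "\n")
  invisible(x)
}

#' Serialize a tracking report to JSON
#'
#' Fixed-precision serialization so identical runs produce bit-identical
#' report files.
#' @param report a `tracking_report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  rows <- lapply(report$rows, function(s) {
    list(n = s$n, mean = round(s$mean, 9), std = round(s$std, 9),
         mean_norm = round(s$mean_norm, 9), std_norm = round(s$std_norm, 9))
  })
  jsonlite::write_json(list(rows = rows, n_frames = report$n_frames,
                            n_failed = as.list(report$n_failed),
                            n_ambiguous = as.list(report$n_ambiguous)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build a pipeline configuration from a YAML file
#'
#' Schema (`schema: 1`): keys `camera`, `cluster`, `calibration`,
#' `observations`, `ir_stream` (file paths, relative to the YAML file),
#' `ir_cluster` (optional path or built-in default), `T_world2cam`
#' (`{quat, t}`), `method`, `seed`, `filter: {window, polyorder}`,
#' `resample_rate_hz`, `us_image: {fov, depth}`.
#' @param path YAML config path.
#' @export
read_pipeline_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  need <- function(key) {
    p <- y[[key]]
    st_assert(!is.null(p), "BadConfig", "config key '%s' is missing", key)
    p <- resolve(p)
    st_assert(file.exists(p), "BadConfig", "%s file not found: %s", key, p)
    p
  }
  ir_cluster <- if (is.null(y$ir_cluster)) ir_cluster_model() else {
    j <- jsonlite::read_json(resolve(y$ir_cluster), simplifyVector = TRUE)
    pl <- j$points_local
    pl <- if (is.list(pl)) do.call(rbind, lapply(pl, unlist)) else as.matrix(pl)
    ir_cluster_model(pl, j$labels)
  }
  T_w2c <- if (is.null(y$T_world2cam)) se3_identity() else {
    rigid_transform(quat_to_rot(unlist(y$T_world2cam$quat)),
                    unlist(y$T_world2cam$t))
  }
  us <- y$us_image
  pipeline_config(
    frames = read_observations_jsonl(need("observations")),
    camera = read_camera_json(need("camera")),
    model = read_cluster_json(need("cluster")),
    calibration = read_calibration_json(need("calibration")),
    ir = read_ir_csv(need("ir_stream")),
    ir_cluster = ir_cluster,
    T_world2cam = T_w2c,
    method = if (is.null(y$method)) "both" else y$method,
    params = pose_params(seed = if (is.null(y$seed)) 1L else y$seed),
    filter_window = if (is.null(y$filter$window)) 15L else y$filter$window,
    filter_polyorder = if (is.null(y$filter$polyorder)) 3L else y$filter$polyorder,
    spec = us_image_spec(fov = if (is.null(us$fov)) 38 else us$fov,
                         depth = if (is.null(us$depth)) 30 else us$depth))
}
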