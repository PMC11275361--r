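#' Read / write pose streams as CSV
#'
#' Format: header `t,tx,ty,tz,qw,qx,qy,qz`, one row per sample; times in
#' seconds, translations in mm, rotations as hemisphere-normalized unit
#' quaternions. Values are written at full double precision (15 significant
#' digits) so a write-read round trip is lossless; quaternions are
#' re-normalized on read, with a warning if their norm drifted by more
#' than 1e-6.
#'
#' @param path CSV file path.
#' @param rate_hint attached to the returned stream.
#' @return `read_pose_csv`: a [pose_stream()] (or an empty-stream stub of
#'   class `pose_stream` when the file has a header and no rows).
#' @export
read_pose_csv <- function(path, rate_hint = NA_real_) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expected <- c("t", "tx", "ty", "tz", "qw", "qx", "qy", "qz")
  st_assert(identical(trimws(header), expected), "MalformedHeader",
            "expected header %s", paste(expected, collapse = ","))
  df <- utils::read.csv(path, colClasses = "numeric")
  if (nrow(df) == 0) {
    return(structure(list(timestamps = numeric(0), poses = list(),
                          rate_hint = rate_hint), class = "pose_stream"))
  }
  st_assert(all(diff(df$t) > 0), "NonMonotoneTimestamps",
            "timestamps in %s are not strictly increasing", path)
  poses <- lapply(seq_len(nrow(df)), function(i) {
    q <- c(df$qw[i], df$qx[i], df$qy[i], df$qz[i])
    drift <- abs(vnorm(q) - 1)
    if (drift > 1e-6) {
      warning(sprintf("quaternion norm drift %.2e at row %d; re-normalizing",
                      drift, i))
    }
    rigid_transform(quat_to_rot(q), c(df$tx[i], df$ty[i], df$tz[i]))
  })
  pose_stream(df$t, poses, rate_hint)
}

#' @rdname read_pose_csv
#' @param stream a [pose_stream()].
#' @export
write_pose_csv <- function(stream, path) {
  stopifnot(inherits(stream, "pose_stream"))
  rows <- vapply(seq_along(stream$timestamps), function(i) {
    p <- stream$poses[[i]]
    q <- rot_to_quat(p$R)
    paste(formatC(c(stream$timestamps[i], p$t, q), format = "g", digits = 15),
          collapse = ",")
  }, "")
  writeLines(c("t,tx,ty,tz,qw,qx,qy,qz", rows), path)
  invisible(path)
}

#' Read / write observation frames as JSON-lines
#'
#' One JSON object per line:
#' `{"t": <s>, "detections": [{"id": <int>, "corners": [[u,v] x 4]}, ...]}`.
#' Frames with zero detections are preserved. Duplicate marker ids within a
#' frame are rejected on read.
#'
#' @param path JSONL file path.
#' @return `read_observations_jsonl`: list of [observation_frame()]s.
#' @export
read_observations_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    j <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = FALSE),
                  error = function(e) st_stop("MalformedRecord",
                                              "unparseable JSONL record: %s", conditionMessage(e)))
    st_assert(!is.null(j$t), "MalformedRecord", "record lacks a timestamp 't'")
    dets <- lapply(j$detections, function(d) {
      list(id = d$id,
           corners = matrix(unlist(d$corners), ncol = 2, byrow = TRUE))
    })
    observation_frame(j$t, dets)
  })
}

#' @rdname read_observations_jsonl
#' @param frames list of [observation_frame()]s.
#' @export
write_observations_jsonl <- function(frames, path) {
  lines <- vapply(frames, function(fr) {
    dets <- lapply(fr$detections, function(d) {
      list(id = d$id,
           corners = lapply(seq_len(4), function(i) d$corners[i, ]))
    })
    jsonlite::toJSON(list(t = fr$timestamp, detections = dets),
                     auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an IR marker stream as CSV
#'
#' Long format: `t,marker,x,y,z` (seconds, label, world-frame mm).
#' @param path CSV file path.
#' @export
read_ir_csv <- function(path) {
  df <- utils::read.csv(path)
  st_assert(identical(names(df), c("t", "marker", "x", "y", "z")),
            "MalformedHeader", "expected header t,marker,x,y,z")
  ts <- sort(unique(df$t))
  labels <- unique(df$marker)
  pts <- lapply(ts, function(tt) {
    sub <- df[df$t == tt, ]
    sub <- sub[match(labels, sub$marker), ]
    as.matrix(sub[, c("x", "y", "z")])
  })
  structure(list(timestamps = ts, points = pts, labels = labels),
            class = "ir_stream")
}

#' @rdname read_ir_csv
#' @param ir an `ir_stream`.
#' @export
write_ir_csv <- function(ir, path) {
  stopifnot(inherits(ir, "ir_stream"))
  rows <- unlist(lapply(seq_along(ir$timestamps), function(i) {
    vapply(seq_len(nrow(ir$points[[i]])), function(m) {
      paste(c(formatC(ir$timestamps[i], format = "g", digits = 15),
              ir$labels[m],
              formatC(ir$points[[i]][m, ], format = "g", digits = 15)),
            collapse = ",")
    }, "")
  }))
  writeLines(c("t,marker,x,y,z", rows), path)
  invisible(path)
}

#' Read / write a calibration snapshot as JSON
#' @param path file path.
#' @export
read_snapshot_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf <- function(x) rigid_transform(quat_to_rot(x$quat), x$t)
  dw <- j$distal_wire_px
  dw <- if (is.list(dw)) do.call(rbind, lapply(dw, unlist)) else as.matrix(dw)
  calibration_snapshot(tf(j$T_cam2dod), tf(j$T_cam2cal),
                       j$cross_point_px, dw,
                       j$proximal_depth, j$distal_depth, j$wire_spacing,
                       j$us_image_width_px,
                       isTRUE(j$multiple_proximal_echoes))
}

#' @rdname read_snapshot_json
#' @param snapshot a [calibration_snapshot()].
#' @export
write_snapshot_json <- function(snapshot, path) {
  tf <- function(T) list(quat = rot_to_quat(T$R), t = T$t)
  jsonlite::write_json(
    list(T_cam2dod = tf(snapshot$T_cam2dod), T_cam2cal = tf(snapshot$T_cam2cal),
         cross_point_px = snapshot$cross_point_px,
         distal_wire_px = lapply(seq_len(nrow(snapshot$distal_wire_px)),
                                 function(i) snapshot$distal_wire_px[i, ]),
         proximal_depth = snapshot$proximal_depth,
         distal_depth = snapshot$distal_depth,
         wire_spacing = snapshot$wire_spacing,
         us_image_width_px = snapshot$us_image_width_px,
         multiple_proximal_echoes = snapshot$multiple_proximal_echoes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a mapped pixel point set as ASCII PLY
#' @param pts n x 3 matrix, mm.
#' @param path output file.
#' @export
write_ply <- function(pts, path) {
  pts <- as.matrix(pts)
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nrow(pts)),
              "property float x", "property float y", "property float z",
              "end_header")
  body <- apply(pts, 1, function(p) paste(formatC(p, format = "g", digits = 9),
                                          collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}
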