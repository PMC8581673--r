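# The per-frame tracking pipeline and whole-video tracking.
#
# Per frame: mask to the tracking area -> detect at a low threshold ->
# keep the highest-confidence box -> enlarge it 1.5x so it covers the whole
# animal -> background subtraction inside the enlarged box -> centroid of
# the largest foreground component.  Two reference baselines are selectable
# through the config because the comparison against them is part of the
# method's evidence: background subtraction over the whole arena
# ("bg_only") and the raw detector box center ("box_center").

#' Tracking configuration
#'
#' @param threshold Detector confidence threshold (default 0.25 — low on
#'   purpose; arbitration happens via highest-p selection).
#' @param enlarge_factor Box enlargement about its center (default 1.5).
#' @param method `"hybrid"` (detector + subtraction in the box),
#'   `"bg_only"`, or `"box_center"`.
#' @param px_per_cm Optional calibration scalar for physical units.
#' @param interpolate_gaps Maximum run of undetected frames to bridge
#'   linearly after tracking; 0 (default) leaves gaps for manual
#'   correction.
#' @return A `bhv_trackcfg` list.
#' @export
track_config <- function(threshold = 0.25, enlarge_factor = 1.5,
                         method = c("hybrid", "bg_only", "box_center"),
                         px_per_cm = NA_real_, interpolate_gaps = 0) {
  method <- match.arg(method)
  if (enlarge_factor < 1) stopf("track_config: enlarge_factor must be >= 1")
  structure(list(threshold = threshold, enlarge_factor = enlarge_factor,
                 method = method, px_per_cm = px_per_cm,
                 interpolate_gaps = interpolate_gaps),
            class = "bhv_trackcfg")
}

#' Select the best detection
#'
#' The detection with the highest confidence `p` wins; ties are broken by
#' larger box area, then by earlier position in the list.
#'
#' @param dets Detections data frame (sorted or not; possibly empty).
#' @return A one-row detection data frame, or `NULL` when empty.
#' @export
select_detection <- function(dets) {
  if (is.null(dets) || nrow(dets) == 0) return(NULL)
  area <- dets$w * dets$h
  ord <- order(-dets$p, -area, seq_len(nrow(dets)))
  dets[ord[1], , drop = FALSE]
}

#' Enlarge a bounding box about its center
#'
#' Width and height are scaled by `factor` (default 1.5, enough to cover the
#' whole animal when the raw box is tight), corners are rounded outward so
#' coverage never shrinks, and the result is clamped to the frame.
#'
#' @param box `c(x, y, w, h)`.
#' @param factor Scale factor >= 1.
#' @param frame_size `(height, width)`.
#' @return An integer-cornered box `c(x, y, w, h)`.
#' @export
enlarge_box <- function(box, factor = 1.5, frame_size) {
  if (factor < 1) stopf("enlarge_box: factor must be >= 1")
  cx <- box[["x"]] + box[["w"]] / 2
  cy <- box[["y"]] + box[["h"]] / 2
  nw <- box[["w"]] * factor; nh <- box[["h"]] * factor
  out <- c(x = floor(cx - nw / 2), y = floor(cy - nh / 2),
           w = ceiling(cx + nw / 2) - floor(cx - nw / 2),
           h = ceiling(cy + nh / 2) - floor(cy - nh / 2))
  bbox_clamp(out, frame_size)
}

track_point <- function(frame_index, centroid = NULL, status = "undetected",
                        p = NA_real_, box = NULL) {
  data.frame(frame = frame_index,
             x = if (is.null(centroid)) NA_real_ else centroid[[1]],
             y = if (is.null(centroid)) NA_real_ else centroid[[2]],
             status = status, p = p,
             box_x = if (is.null(box)) NA_real_ else box[["x"]],
             box_y = if (is.null(box)) NA_real_ else box[["y"]],
             box_w = if (is.null(box)) NA_real_ else box[["w"]],
             box_h = if (is.null(box)) NA_real_ else box[["h"]])
}

#' Track a single frame
#'
#' Runs the per-frame pipeline and returns one track point. Status is
#' `"tracked"` when a foreground centroid was found inside the enlarged
#' box, `"fallback_box_center"` when the detector fired but subtraction
#' found no foreground (the centroid is then the enlarged-box center), and
#' `"undetected"` when no detection survived the threshold.
#'
#' @param frame `(h, w, 3)` numeric frame at working size.
#' @param detector A `bhv_detector` (ignored for `method = "bg_only"`).
#' @param bg A [estimate_background()] model.
#' @param area Optional [tracking_area()].
#' @param cfg A [track_config()].
#' @param frame_index 0-based frame index (defaults to the frame's
#'   attribute).
#' @return A one-row track-point data frame.
#' @export
track_frame <- function(frame, detector, bg, area = NULL,
                        cfg = track_config(), frame_index = NULL) {
  frame_index <- frame_index %||% attr(frame, "frame_index") %||% 0L
  d <- dim(frame)[1:2]
  masked <- if (!is.null(area)) apply_tracking_area(frame, area) else frame
  if (cfg$method == "bg_only") {
    fg <- subtract_foreground(masked, bg, bbox(0, 0, d[2], d[1]))
    if (fg$pixel_count == 0)
      return(track_point(frame_index, status = "undetected"))
    return(track_point(frame_index, centroid = fg$centroid, status = "tracked"))
  }
  dets <- detect(detector, masked, threshold = cfg$threshold,
                 frame_index = frame_index)
  sel <- select_detection(dets)
  if (is.null(sel)) return(track_point(frame_index, status = "undetected"))
  raw_box <- bbox_round_out(c(x = sel$x, y = sel$y, w = sel$w, h = sel$h))
  if (cfg$method == "box_center") {
    ctr <- c(x = raw_box[["x"]] + (raw_box[["w"]] - 1) / 2,
             y = raw_box[["y"]] + (raw_box[["h"]] - 1) / 2)
    return(track_point(frame_index, centroid = ctr, status = "tracked",
                       p = sel$p, box = raw_box))
  }
  big <- enlarge_box(raw_box, cfg$enlarge_factor, d)
  fg <- subtract_foreground(masked, bg, big)
  if (fg$pixel_count > 0) {
    track_point(frame_index, centroid = fg$centroid, status = "tracked",
                p = sel$p, box = big)
  } else {
    ctr <- c(x = big[["x"]] + (big[["w"]] - 1) / 2,
             y = big[["y"]] + (big[["h"]] - 1) / 2)
    track_point(frame_index, centroid = ctr, status = "fallback_box_center",
                p = sel$p, box = big)
  }
}

#' Track a whole video
#'
#' One track point per frame, in order; a per-status summary is reported at
#' the end. Deterministic for a fixed detector.
#'
#' @param seq A [frame_sequence()].
#' @param detector A `bhv_detector` (NULL allowed for `method = "bg_only"`).
#' @param bg A background model; estimated from `seq` (temporal median) when
#'   NULL.
#' @param area Optional [tracking_area()].
#' @param cfg A [track_config()].
#' @param verbose Report the status summary (default TRUE).
#' @return A `bhv_trajectory`.
#' @export
track_video <- function(seq, detector, bg = NULL, area = NULL,
                        cfg = track_config(), verbose = TRUE) {
  if (is.null(bg)) bg <- estimate_background(seq)
  n <- n_frames(seq)
  pts <- vector("list", n)
  for (i in seq_len(n)) {
    pt <- try(track_frame(get_frame(seq, i), detector, bg, area, cfg,
                          frame_index = i - 1L), silent = TRUE)
    if (inherits(pt, "try-error"))
      stopf("track_video: frame %d failed: %s", i - 1L, attr(pt, "condition")$message)
    pts[[i]] <- pt
  }
  pts <- do.call(rbind, pts)
  traj <- structure(list(points = pts, fps = seq$fps,
                         px_per_cm = cfg$px_per_cm,
                         working_size = seq$working_size,
                         provenance = list(cfg = unclass(cfg),
                                           detector = detector$backend %||% "none",
                                           source = seq$path)),
                    class = "bhv_trajectory")
  if (cfg$interpolate_gaps > 0)
    traj <- interpolate_gaps(traj, cfg$interpolate_gaps)
  if (verbose) {
    cnt <- table(traj$points$status)
    message("track_video: ", paste(sprintf("%s=%d", names(cnt), cnt),
                                   collapse = ", "))
  }
  traj
}

#' @export
as.data.frame.bhv_trajectory <- function(x, ...) x$points

#' @export
print.bhv_trajectory <- function(x, ...) {
  cnt <- table(x$points$status)
  cat(sprintf("<bhv_trajectory> %d frames at %.6g fps (%s)\n",
              nrow(x$points), x$fps,
              paste(sprintf("%s %d", names(cnt), cnt), collapse = ", ")))
  invisible(x)
}

#' @export
summary.bhv_trajectory <- function(object, ...) {
  pts <- object$points
  known <- sum(!is.na(pts$x))
  out <- list(n_frames = nrow(pts), known = known,
              duration_s = nrow(pts) / object$fps,
              status = table(pts$status))
  if (known >= 2) {
    kin <- try(kinematics(object), silent = TRUE)
    if (!inherits(kin, "try-error")) out$totals <- kin$totals
  }
  class(out) <- "summary.bhv_trajectory"
  out
}

#' @export
print.summary.bhv_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames (%.1f s), %d with centroid\n",
              x$n_frames, x$duration_s, x$known))
  print(x$status)
  if (!is.null(x$totals))
    cat(sprintf("Total distance %.1f %s, mean speed %.2f %s\n",
                x$totals$total_distance, x$totals$distance_unit,
                x$totals$mean_speed, x$totals$speed_unit))
  invisible(x)
}

#' @export
plot.bhv_trajectory <- function(x, ...) {
  pts <- x$points
  ws <- x$working_size %||% c(max(pts$y, na.rm = TRUE), max(pts$x, na.rm = TRUE))
  plot(NA, xlim = c(0, ws[2]), ylim = c(ws[1], 0), xlab = "x (px)",
       ylab = "y (px)", asp = 1, ...)
  lines(pts$x, pts$y, col = "steelblue")
  bad <- pts$status %in% c("fallback_box_center", "manual")
  points(pts$x[bad], pts$y[bad], col = "orange", pch = 16, cex = 0.5)
  invisible(x)
}

#' Apply manual corrections to a trajectory
#'
#' Corrected frames get the supplied centroid and status `"manual"`; all
#' other points are untouched and the input trajectory is not modified.
#' Applying corrections in several batches gives the same result as one
#' batch.
#'
#' @param traj A `bhv_trajectory`.
#' @param corrections Data frame with columns `frame` (0-based), `x`, `y`.
#' @return The corrected `bhv_trajectory`.
#' @export
manual_correct <- function(traj, corrections) {
  corrections <- as.data.frame(corrections)
  if (nrow(corrections) == 0) return(traj)
  stopifnot(all(c("frame", "x", "y") %in% names(corrections)))
  idx <- match(corrections$frame, traj$points$frame)
  if (anyNA(idx))
    stopf("manual_correct: frame index out of range: %s",
          paste(corrections$frame[is.na(idx)], collapse = ", "))
  traj$points$x[idx] <- corrections$x
  traj$points$y[idx] <- corrections$y
  traj$points$status[idx] <- "manual"
  traj
}

#' Bridge short undetected gaps by linear interpolation
#'
#' Gaps of at most `max_gap` undetected frames flanked by known centroids
#' are filled linearly and marked `"manual"` (they are automatic
#' corrections, not tracker output). Off by default in [track_config()]:
#' the intended route for undetected frames is [collect_failures()] and
#' relabeling.
#'
#' @param traj A `bhv_trajectory`.
#' @param max_gap Longest gap (frames) to bridge.
#' @return The interpolated trajectory.
#' @export
interpolate_gaps <- function(traj, max_gap = 5) {
  pts <- traj$points
  known <- which(!is.na(pts$x))
  if (length(known) < 2) return(traj)
  for (i in seq_len(length(known) - 1)) {
    a <- known[i]; b <- known[i + 1]
    gap <- b - a - 1
    if (gap >= 1 && gap <= max_gap) {
      t <- seq_len(gap) / (gap + 1)
      idx <- (a + 1):(b - 1)
      pts$x[idx] <- pts$x[a] + t * (pts$x[b] - pts$x[a])
      pts$y[idx] <- pts$y[a] + t * (pts$y[b] - pts$y[a])
      pts$status[idx] <- "manual"
    }
  }
  traj$points <- pts
  traj
}

#' Collect failed frames for the feedback loop
#'
#' Returns the frames whose status is `"undetected"`, whose confidence fell
#' below `criteria$p_min`, or whose single-frame displacement exceeds
#' `criteria$jump_px` (flagged `"incorrect"`). With `out_dir` set, the
#' frames are written as PNGs together with an annotation CSV template
#' (prefilled with the tracked box when available) so they can be relabeled
#' and merged into the training set via [read_annotations()] — the feedback
#' loop that turns tracking failures into new training data.
#'
#' @param traj A `bhv_trajectory`.
#' @param seq The matching [frame_sequence()].
#' @param criteria List with `p_min` (default 0) and `jump_px` (default 40,
#'   tuned for 360x640 working frames).
#' @param out_dir Optional export directory.
#' @return A list: `indices` (0-based), `reasons` data frame, `frames`
#'   (list of image arrays).
#' @export
collect_failures <- function(traj, seq, criteria = list(), out_dir = NULL) {
  p_min <- criteria$p_min %||% 0
  jump_px <- criteria$jump_px %||% 40
  pts <- traj$points
  if (nrow(pts) != n_frames(seq))
    stopf("collect_failures: trajectory and sequence lengths differ")
  reasons <- list()
  add <- function(frame, reason)
    reasons[[length(reasons) + 1]] <<- data.frame(frame = frame, reason = reason)
  for (i in seq_len(nrow(pts))) {
    if (pts$status[i] == "undetected") add(pts$frame[i], "undetected")
    else if (!is.na(pts$p[i]) && pts$p[i] < p_min) add(pts$frame[i], "low_confidence")
  }
  if (is.finite(jump_px)) {
    for (i in 2:nrow(pts)) {
      if (!is.na(pts$x[i]) && !is.na(pts$x[i - 1])) {
        d <- sqrt((pts$x[i] - pts$x[i - 1])^2 + (pts$y[i] - pts$y[i - 1])^2)
        if (d > jump_px) add(pts$frame[i], "incorrect")
      }
    }
  }
  reasons <- if (length(reasons)) do.call(rbind, reasons) else
    data.frame(frame = integer(0), reason = character(0))
  reasons <- reasons[!duplicated(reasons$frame), , drop = FALSE]
  reasons <- reasons[order(reasons$frame), , drop = FALSE]
  frames <- lapply(reasons$frame, function(f) get_frame(seq, f + 1L))
  if (!is.null(out_dir) && nrow(reasons) > 0) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(nrow(reasons)))
      png::writePNG(frames[[k]],
                    file.path(out_dir, sprintf("frame_%06d.png", reasons$frame[k])))
    tmpl <- merge(reasons["frame"], pts[c("frame", "box_x", "box_y", "box_w", "box_h")],
                  by = "frame")
    ann <- data.frame(video = seq$path %||% "video", frame = tmpl$frame,
                      x = tmpl$box_x, y = tmpl$box_y, w = tmpl$box_w,
                      h = tmpl$box_h, class = "relabel_me")
    write.csv(ann, file.path(out_dir, "annotations_template.csv"),
              row.names = FALSE)
  }
  list(indices = reasons$frame, reasons = reasons, frames = frames)
}

#' Read/write trajectories as CSV
#'
#' Columns: frame, x, y, status, p, box_x, box_y, box_w, box_h; fps,
#' calibration and provenance go to a YAML sidecar.
#'
#' @param traj A `bhv_trajectory`.
#' @param path CSV path.
#' @return `path` invisibly / the restored trajectory.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(traj$points, path, row.names = FALSE)
  yaml::write_yaml(list(fps = traj$fps, px_per_cm = traj$px_per_cm,
                        working_size = as.integer(traj$working_size),
                        provenance = traj$provenance),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  pts <- read.csv(path, stringsAsFactors = FALSE)
  meta <- if (file.exists(paste0(path, ".yaml")))
    yaml::read_yaml(paste0(path, ".yaml")) else list()
  structure(list(points = pts, fps = meta$fps %||% 30,
                 px_per_cm = meta$px_per_cm %||% NA_real_,
                 working_size = unlist(meta$working_size) %||% NULL,
                 provenance = meta$provenance %||% list()),
            class = "bhv_trajectory")
}
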