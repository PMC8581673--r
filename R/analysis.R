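# Trajectory analytics: kinematics, occupancy heat maps, region dwell,
# error to ground truth, and two-animal color-marker identity.

as_centroid_table <- function(x) {
  if (inherits(x, "bhv_trajectory")) return(x$points[c("frame", "x", "y")])
  df <- as.data.frame(x)
  if (!all(c("frame", "x", "y") %in% names(df)))
    stopf("expected a trajectory or a (frame, x, y) table")
  if ("target" %in% names(df) && length(unique(df$target)) > 1)
    stopf("table contains %d targets; subset to one first",
          length(unique(df$target)))
  df[c("frame", "x", "y")]
}

#' Per-frame kinematics of a trajectory
#'
#' Step distance is the Euclidean displacement between centroids of
#' consecutive frames where both are known — gaps are excluded, not bridged,
#' so occlusions do not inflate the travelled distance. Speed is
#' `distance * fps`, converted to cm/s when the trajectory carries a
#' `px_per_cm` calibration.
#'
#' @param traj A `bhv_trajectory`.
#' @param median_window Odd window for an optional running-median filter on
#'   the speed series (0 = off, the default).
#' @return A list: `steps` (frame_from, frame_to, distance, speed),
#'   `totals` (total_distance, mean_speed, total_time_s, n_steps, units).
#' @export
kinematics <- function(traj, median_window = 0) {
  pts <- traj$points
  if (nrow(pts) < 2) stopf("kinematics: need >= 2 frames")
  ok <- !is.na(pts$x)
  i <- which(ok[-nrow(pts)] & ok[-1] &
             diff(pts$frame) == 1L)
  if (length(i) == 0) stopf("kinematics: no valid steps")
  dx <- pts$x[i + 1] - pts$x[i]
  dy <- pts$y[i + 1] - pts$y[i]
  dist <- sqrt(dx^2 + dy^2)
  calibrated <- is.finite(traj$px_per_cm %||% NA_real_)
  if (calibrated) dist <- dist / traj$px_per_cm
  speed <- dist * traj$fps
  if (median_window >= 3)
    speed <- runmed(speed, k = median_window %/% 2 * 2 + 1)
  list(steps = data.frame(frame_from = pts$frame[i], frame_to = pts$frame[i + 1],
                          distance = dist, speed = speed),
       totals = list(total_distance = sum(dist), mean_speed = mean(speed),
                     total_time_s = nrow(pts) / traj$fps, n_steps = length(i),
                     distance_unit = if (calibrated) "cm" else "px",
                     speed_unit = if (calibrated) "cm/s" else "px/s"))
}

#' Spatial occupancy heat map
#'
#' Time mode accumulates `1/fps` seconds into the bin holding each known
#' centroid, so the grid mass equals the tracked time. Speed mode averages
#' the step speed over the visits to each bin; bins never visited are `NA`,
#' not zero.
#'
#' @param traj A `bhv_trajectory`.
#' @param mode `"time"` (seconds) or `"speed"` (mean step speed).
#' @param bin_px Square bin side in pixels (default 16 at the working
#'   resolution).
#' @param extent `(height, width)` of the mapped region; defaults to the
#'   trajectory's working size.
#' @return A `bhv_heatmap`: `grid` matrix (rows = y bins), `bin_px`, `mode`,
#'   `extent`.
#' @export
occupancy_heatmap <- function(traj, mode = c("time", "speed"), bin_px = 16,
                              extent = NULL) {
  mode <- match.arg(mode)
  if (bin_px < 1) stopf("occupancy_heatmap: bin_px must be >= 1")
  extent <- extent %||% traj$working_size
  if (is.null(extent)) stopf("occupancy_heatmap: extent unknown")
  nby <- ceiling(extent[1] / bin_px); nbx <- ceiling(extent[2] / bin_px)
  pts <- traj$points
  known <- pts[!is.na(pts$x), , drop = FALSE]
  bi <- function(v, nb) pmin(nb, pmax(1, floor(v / bin_px) + 1))
  if (mode == "time") {
    grid <- matrix(0, nby, nbx)
    if (nrow(known) > 0) {
      tab <- table(factor(bi(known$y, nby), levels = 1:nby),
                   factor(bi(known$x, nbx), levels = 1:nbx))
      grid <- matrix(as.numeric(tab), nby, nbx) / traj$fps
    }
  } else {
    kin <- kinematics(traj)
    sums <- matrix(0, nby, nbx); cnts <- matrix(0, nby, nbx)
    to <- match(kin$steps$frame_to, pts$frame)
    for (k in seq_len(nrow(kin$steps))) {
      r <- bi(pts$y[to[k]], nby); c <- bi(pts$x[to[k]], nbx)
      sums[r, c] <- sums[r, c] + kin$steps$speed[k]
      cnts[r, c] <- cnts[r, c] + 1
    }
    grid <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  }
  structure(list(grid = grid, bin_px = bin_px, mode = mode, extent = extent),
            class = "bhv_heatmap")
}

#' @export
print.bhv_heatmap <- function(x, ...) {
  cat(sprintf("<bhv_heatmap:%s> %dx%d bins of %d px; mass %.3f\n", x$mode,
              nrow(x$grid), ncol(x$grid), x$bin_px, sum(x$grid, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.bhv_heatmap <- function(x, ...) {
  g <- x$grid
  image(x = (seq_len(ncol(g)) - 0.5) * x$bin_px,
        y = (seq_len(nrow(g)) - 0.5) * x$bin_px,
        z = t(g), ylim = c(nrow(g) * x$bin_px, 0),
        xlab = "x (px)", ylab = "y (px)", asp = 1,
        col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(x)
}

#' Dwell time and visit counts per named region
#'
#' Time per region counts frames whose centroid lies inside the region
#' polygon (boundary included) divided by fps; overlapping regions each
#' accumulate. A visit is a maximal run of consecutive frames inside the
#' region. Undetected frames count for no region.
#'
#' @param traj A `bhv_trajectory`.
#' @param regions Named list of polygons (`n x 2` matrices, columns x, y) or
#'   rectangles `c(x, y, w, h)`.
#' @return Data frame: region, time_s, visits, n_frames.
#' @export
region_dwell <- function(traj, regions) {
  pts <- traj$points
  known <- !is.na(pts$x)
  rows <- lapply(names(regions), function(nm) {
    poly <- regions[[nm]]
    if (is.numeric(poly) && is.null(dim(poly)) && length(poly) == 4) {
      poly <- cbind(c(poly[1], poly[1] + poly[3], poly[1] + poly[3], poly[1]),
                    c(poly[2], poly[2], poly[2] + poly[4], poly[2] + poly[4]))
    }
    inside <- rep(FALSE, nrow(pts))
    inside[known] <- pracma::inpolygon(pts$x[known], pts$y[known],
                                       poly[, 1], poly[, 2], boundary = TRUE)
    runs <- rle(inside)
    data.frame(region = nm, time_s = sum(inside) / traj$fps,
               visits = sum(runs$values), n_frames = sum(inside))
  })
  do.call(rbind, rows)
}

#' Error to ground truth
#'
#' Per-frame Euclidean distance between two centroid series (typically a
#' tracked trajectory and a reference) over the frames where both are
#' known; frames missing in either series are reported as non-covered,
#' never as zero error. The function is symmetric in its two inputs.
#'
#' @param traj,truth A `bhv_trajectory` or a `(frame, x, y)` table (e.g.
#'   the generator's ground truth, subset to one target).
#' @return A list: `per_frame` (frame, distance, covered), `mean`, `max`,
#'   `coverage` (fraction of the overlapping frame range covered by both).
#' @export
error_to_ground_truth <- function(traj, truth) {
  a <- as_centroid_table(traj)
  b <- as_centroid_table(truth)
  lo <- max(min(a$frame), min(b$frame))
  hi <- min(max(a$frame), max(b$frame))
  if (lo > hi) stopf("error_to_ground_truth: frame ranges do not overlap")
  frames <- lo:hi
  ia <- match(frames, a$frame); ib <- match(frames, b$frame)
  covered <- !is.na(ia) & !is.na(ib) &
    !is.na(a$x[ia]) & !is.na(b$x[ib])
  dist <- rep(NA_real_, length(frames))
  dist[covered] <- sqrt((a$x[ia[covered]] - b$x[ib[covered]])^2 +
                        (a$y[ia[covered]] - b$y[ib[covered]])^2)
  list(per_frame = data.frame(frame = frames, distance = dist,
                              covered = covered),
       mean = mean(dist[covered]), max = max(dist[covered]),
       coverage = mean(covered))
}

#' Default color-marker definitions
#'
#' HSV ranges for the stock "blue" and "green" back markers; hue is on the
#' `[0, 1)` circle.
#'
#' @return Named list of marker definitions (`h = c(lo, hi)`, `s_min`,
#'   `v_min`).
#' @export
marker_colors <- function() {
  list(blue = list(h = c(0.50, 0.75), s_min = 0.35, v_min = 0.20),
       green = list(h = c(0.20, 0.45), s_min = 0.35, v_min = 0.20))
}

#' Assign color-marker identities to detections
#'
#' For multi-animal tracking each animal wears a distinct color sticker.
#' Every detection is assigned the marker with the largest count of in-box
#' pixels falling inside the marker's HSV range, greedily by descending
#' count so that no two detections share an identity; detections without
#' enough marker pixels are labeled `"unknown"`.
#'
#' @param frame `(h, w, 3)` numeric frame.
#' @param detections Detections data frame (>= 1 row).
#' @param markers Named marker definitions; hue ranges must not overlap.
#' @param min_pixels Minimum marker-pixel count for an assignment
#'   (default 10).
#' @return Character vector of identities, one per detection row.
#' @export
color_identity <- function(frame, detections, markers = marker_colors(),
                           min_pixels = 10) {
  if (nrow(detections) == 0) stopf("color_identity: need >= 1 detection")
  nm <- names(markers)
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1)) for (j in (i + 1):length(nm)) {
      hi <- markers[[i]]$h; hj <- markers[[j]]$h
      if (hi[1] < hj[2] && hj[1] < hi[2])
        stopf("color_identity: hue ranges of '%s' and '%s' overlap", nm[i], nm[j])
    }
  }
  d <- dim(frame)[1:2]
  counts <- matrix(0, nrow(detections), length(nm),
                   dimnames = list(NULL, nm))
  for (i in seq_len(nrow(detections))) {
    box <- bbox_clamp(bbox_round_out(c(x = detections$x[i], y = detections$y[i],
                                       w = detections$w[i], h = detections$h[i])), d)
    if (is.null(box)) next
    sub <- frame[box[["y"]] + seq_len(box[["h"]]),
                 box[["x"]] + seq_len(box[["w"]]), , drop = FALSE]
    hsv <- frame_to_hsv(sub)
    for (m in nm) {
      mk <- markers[[m]]
      hit <- hsv[, , 1] >= mk$h[1] & hsv[, , 1] <= mk$h[2] &
        hsv[, , 2] >= mk$s_min & hsv[, , 3] >= mk$v_min
      counts[i, m] <- sum(hit)
    }
  }
  ident <- rep("unknown", nrow(detections))
  free_det <- rep(TRUE, nrow(detections))
  free_mk <- setNames(rep(TRUE, length(nm)), nm)
  repeat {
    cand <- which(outer(free_det, free_mk) & counts >= min_pixels,
                  arr.ind = TRUE)
    if (nrow(cand) == 0) break
    best <- cand[which.max(counts[cand]), ]
    ident[best[1]] <- nm[best[2]]
    free_det[best[1]] <- FALSE
    free_mk[best[2]] <- FALSE
  }
  ident
}
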