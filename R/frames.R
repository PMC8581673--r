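# Video / image-sequence ingestion at a fixed working resolution, tracking
# area masking, and labeled-video export.
#
# Frames are held internally as 8-bit raw arrays of dim (h, w, 3); accessors
# return numeric arrays in [0, 1].  The default working resolution is
# 360 x 640 x 3: behavior videos are resized at ingestion so that every later
# stage runs at a fixed, cheap resolution.

#' Construct a frame sequence
#'
#' @param frames List of color frames, each an `(h, w, 3)` numeric array in
#'   `[0, 1]` (or an 8-bit raw array of the same shape). All frames must share
#'   one size.
#' @param fps Frames per second; must be positive.
#' @param native_size Original `(height, width)` before any resize; defaults
#'   to the frame size.
#' @param path Source identifier (file path or label).
#' @return An object of class `bhv_frames`.
#' @export
frame_sequence <- function(frames, fps = 30, native_size = NULL, path = NA_character_) {
  if (!is.list(frames) || length(frames) < 1)
    stopf("frame_sequence: need a non-empty list of frames")
  if (!is.numeric(fps) || fps <= 0) stopf("frame_sequence: fps must be > 0")
  frames <- lapply(frames, as_raw_frame)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stopf("frame_sequence: frames differ in size")
  structure(list(
    frames = frames,
    fps = fps,
    native_size = as.integer(native_size %||% d[1:2]),
    working_size = as.integer(d[1:2]),
    path = path
  ), class = "bhv_frames")
}

# Quantize a [0,1] numeric frame to an 8-bit raw array (dims preserved).
as_raw_frame <- function(frame) {
  if (is.raw(frame)) {
    if (length(dim(frame)) != 3 || dim(frame)[3] != 3)
      stopf("frames must be (h, w, 3) arrays")
    return(frame)
  }
  d <- dim(frame)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stopf("frames must be (h, w, 3) arrays")
  r <- as.raw(pmin(255L, pmax(0L, as.integer(round(frame * 255)))))
  dim(r) <- d
  r
}

#' Number of frames in a sequence
#' @param seq A `bhv_frames` object.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(seq$frames)

#' Extract one frame as a numeric array
#'
#' @param seq A `bhv_frames` object.
#' @param i Frame index (1-based, as usual for R containers).
#' @return An `(h, w, 3)` numeric array in `[0, 1]` carrying a
#'   `"frame_index"` attribute with the 0-based frame index (used by the
#'   oracle detector backend).
#' @export
get_frame <- function(seq, i) {
  if (i < 1 || i > length(seq$frames)) stopf("get_frame: index %d out of range", i)
  f <- seq$frames[[i]]
  out <- array(as.integer(f) / 255, dim = dim(f))
  attr(out, "frame_index") <- i - 1L
  out
}

#' @export
print.bhv_frames <- function(x, ...) {
  cat(sprintf("<bhv_frames> %d frames, %dx%d px, %.6g fps (native %dx%d)\n",
              length(x$frames), x$working_size[1], x$working_size[2], x$fps,
              x$native_size[1], x$native_size[2]))
  if (!is.na(x$path)) cat("  source:", x$path, "\n")
  invisible(x)
}

read_one_image <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- switch(ext,
    png = png::readPNG(f),
    tif = , tiff = tiff::readTIFF(f),
    stopf("read_video: unsupported image format '%s' (%s)", ext, f))
  normalize_channels(img)
}

normalize_channels <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) == 2) {
    img <- array(rep(as.numeric(img), 3), dim = c(dim(img) %||% c(length(img), 1), 3))
  } else if (d[3] == 4) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (d[3] == 1) {
    img <- array(rep(img, 3), dim = c(d[1], d[2], 3))
  }
  img
}

#' Read a video (image sequence or multi-page TIFF) at the working resolution
#'
#' Sources are either a directory of numbered PNG/TIFF frames (decoded in
#' filename sort order) or a single multi-page TIFF / single PNG file. Every
#' frame is bilinearly resized to `working_size`; a source already at the
#' working size is passed through untouched.
#'
#' Frame timing is taken from `fps` if given, else from a YAML sidecar
#' `<path>.yaml` with an `fps` field, else it falls back to 30 fps with a
#' message (common webcam default).
#'
#' @param path Directory of frames or video file.
#' @param working_size Target `(height, width)`; default `c(360, 640)`.
#' @param fps Optional frames/second override.
#' @return A [frame_sequence()] object.
#' @export
read_video <- function(path, working_size = c(360, 640), fps = NULL) {
  if (!file.exists(path)) stopf("read_video: cannot read '%s'", path)
  if (any(working_size < 1)) stopf("read_video: working_size must be positive")
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- files[order(basename(files))]
    if (length(files) == 0) stopf("read_video: no decodable frames in '%s'", path)
    raw_frames <- lapply(files, read_one_image)
  } else {
    ext <- tolower(tools::file_ext(path))
    raw_frames <- switch(ext,
      tif = , tiff = {
        pages <- tiff::readTIFF(path, all = TRUE)
        lapply(pages, normalize_channels)
      },
      png = list(read_one_image(path)),
      stopf("read_video: unsupported container '%s'", ext))
    if (length(raw_frames) == 0) stopf("read_video: zero decodable frames in '%s'", path)
  }
  native <- dim(raw_frames[[1]])[1:2]
  frames <- lapply(raw_frames, resize_pixels, target = working_size)
  if (is.null(fps)) {
    sidecar <- paste0(sub("/+$", "", path), ".yaml")
    if (file.exists(sidecar)) {
      meta <- yaml::read_yaml(sidecar)
      fps <- meta$fps
    }
    if (is.null(fps)) {
      fps <- 30
      message("read_video: no frame timing found for '", path,
              "'; assuming 30 fps")
    }
  }
  frame_sequence(frames, fps = fps, native_size = native, path = path)
}

#' Define a tracking area
#'
#' The tracking area is the user-defined region of the frame inside which
#' tracking happens; pixels outside it are overwritten with a background
#' fill color before detection, so that objects outside the maze cannot
#' produce spurious detections or foreground.
#'
#' @param polygon An `n x 2` matrix (columns x, y) of vertices in working
#'   frame pixel coordinates; must be simple (non-self-intersecting) with at
#'   least 3 vertices. A convenience rectangle may be given as
#'   `c(x, y, w, h)`.
#' @param fill_color RGB triple in `[0, 1]` used outside the area; default
#'   black.
#' @return An object of class `bhv_area`.
#' @export
tracking_area <- function(polygon, fill_color = c(0, 0, 0)) {
  if (is.numeric(polygon) && is.null(dim(polygon)) && length(polygon) == 4) {
    x <- polygon[1]; y <- polygon[2]; w <- polygon[3]; h <- polygon[4]
    polygon <- cbind(c(x, x + w - 1, x + w - 1, x),
                     c(y, y, y + h - 1, y + h - 1))
  }
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3)
    stopf("tracking_area: polygon needs >= 3 (x, y) vertices")
  if (any(!is.finite(polygon))) stopf("tracking_area: non-finite vertices")
  if (!polygon_is_simple(polygon)) stopf("tracking_area: polygon self-intersects")
  if (length(fill_color) != 3 || any(fill_color < 0 | fill_color > 1))
    stopf("tracking_area: fill_color must be an RGB triple in [0, 1]")
  structure(list(polygon = polygon, fill_color = as.numeric(fill_color)),
            class = "bhv_area")
}

# Brute-force proper-intersection test between non-adjacent edges.
polygon_is_simple <- function(p) {
  n <- nrow(p)
  seg <- function(i) rbind(p[i, ], p[if (i == n) 1 else i + 1, ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  inter <- function(s1, s2) {
    d1 <- cross(s2[1, ], s2[2, ], s1[1, ]); d2 <- cross(s2[1, ], s2[2, ], s1[2, ])
    d3 <- cross(s1[1, ], s1[2, ], s2[1, ]); d4 <- cross(s1[1, ], s1[2, ], s2[2, ])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n <= 3) return(TRUE)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the closing edge
      if (inter(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

# Rasterize the tracking-area polygon on a frame of size (h, w): a pixel is
# inside when its center lies inside or on the polygon boundary.
area_mask <- function(area, frame_size) {
  h <- frame_size[1]; w <- frame_size[2]
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  inside <- pracma::inpolygon(px, py, area$polygon[, 1], area$polygon[, 2],
                              boundary = TRUE)
  m <- matrix(inside, nrow = h, ncol = w)
  if (!any(m)) stopf("tracking_area: rasterized area has no interior pixel")
  m
}

#' Mask a frame to its tracking area
#'
#' Pixels outside the area polygon are set to the area's fill color; pixels
#' inside are returned unchanged. The input frame is not modified.
#'
#' @param frame An `(h, w, 3)` numeric frame.
#' @param area A [tracking_area()].
#' @return The masked frame.
#' @export
apply_tracking_area <- function(frame, area) {
  d <- dim(frame)
  if (any(area$polygon[, 1] < 0) || any(area$polygon[, 1] > d[2] - 1) ||
      any(area$polygon[, 2] < 0) || any(area$polygon[, 2] > d[1] - 1))
    stopf("apply_tracking_area: polygon extends outside the frame")
  m <- area_mask(area, d[1:2])
  out <- frame
  outside <- !m
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[outside] <- area$fill_color[ch]
    out[, , ch] <- plane
  }
  attr(out, "frame_index") <- attr(frame, "frame_index")
  out
}

#' Write a frame sequence to disk without overlays
#'
#' Multi-page TIFF when `path` ends in `.tif`/`.tiff`, else a directory of
#' numbered PNGs. An `fps` YAML sidecar is written next to the output.
#'
#' @param seq A [frame_sequence()].
#' @param path Output file or directory.
#' @return `path`, invisibly.
#' @export
write_video <- function(seq, path) {
  frames <- lapply(seq_len(n_frames(seq)), function(i) {
    f <- get_frame(seq, i); attr(f, "frame_index") <- NULL; f
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    ok <- try(tiff::writeTIFF(frames, path, bits.per.sample = 8), silent = TRUE)
    if (inherits(ok, "try-error")) stopf("write_video: cannot write '%s'", path)
  } else {
    if (!dir.exists(path) && !dir.create(path, recursive = TRUE, showWarnings = FALSE))
      stopf("write_video: cannot create '%s'", path)
    for (i in seq_along(frames))
      png::writePNG(frames[[i]], file.path(path, sprintf("frame_%06d.png", i)))
  }
  yaml::write_yaml(list(fps = seq$fps), paste0(sub("/+$", "", path), ".yaml"))
  invisible(path)
}

#' Save / load a tracking area as YAML
#' @param area A [tracking_area()].
#' @param path Output file.
#' @return `path`, invisibly (`write_`), or a `bhv_area` (`read_`).
#' @export
write_tracking_area <- function(area, path) {
  yaml::write_yaml(list(polygon = apply(area$polygon, 1, as.list),
                        fill_color = area$fill_color), path)
  invisible(path)
}

#' @rdname write_tracking_area
#' @export
read_tracking_area <- function(path) {
  rec <- yaml::read_yaml(path)
  poly <- do.call(rbind, lapply(rec$polygon, unlist))
  tracking_area(poly, unlist(rec$fill_color))
}

# --- drawing primitives for labeled-video export -------------------------

draw_disc <- function(frame, x, y, r, color) {
  d <- dim(frame)
  xs <- max(0, floor(x - r)):min(d[2] - 1, ceiling(x + r))
  ys <- max(0, floor(y - r)):min(d[1] - 1, ceiling(y + r))
  if (length(xs) == 0 || length(ys) == 0) return(frame)
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  hit <- (gx - x)^2 + (gy - y)^2 <= r^2
  for (ch in 1:3) frame[cbind(gy[hit] + 1, gx[hit] + 1, ch)] <- color[ch]
  frame
}

draw_segment <- function(frame, x1, y1, x2, y2, color, width = 1) {
  n <- max(2, ceiling(max(abs(x2 - x1), abs(y2 - y1))) + 1)
  xs <- seq(x1, x2, length.out = n); ys <- seq(y1, y2, length.out = n)
  for (i in seq_len(n)) frame <- draw_disc(frame, xs[i], ys[i], width / 2, color)
  frame
}

draw_rect_outline <- function(frame, box, color) {
  x1 <- box[["x"]]; y1 <- box[["y"]]
  x2 <- box[["x"]] + box[["w"]] - 1; y2 <- box[["y"]] + box[["h"]] - 1
  frame <- draw_segment(frame, x1, y1, x2, y1, color)
  frame <- draw_segment(frame, x2, y1, x2, y2, color)
  frame <- draw_segment(frame, x2, y2, x1, y2, color)
  draw_segment(frame, x1, y2, x1, y1, color)
}

status_color <- function(status) {
  switch(status,
         tracked = c(0.1, 0.9, 0.1),
         fallback_box_center = c(1.0, 0.6, 0.0),
         manual = c(0.2, 0.4, 1.0),
         undetected = c(1.0, 0.1, 0.1),
         c(1, 1, 1))
}

#' Export a labeled video
#'
#' Overlays the per-frame centroid marker, a trailing trace, the enlarged
#' detection box, a top-edge confidence bar (length proportional to the
#' detector confidence), and a status glyph (undetected frames get a red
#' frame border). Writes a multi-page TIFF when `path` ends in
#' `.tif`/`.tiff`, otherwise a directory of numbered PNG frames.
#'
#' @param seq A [frame_sequence()].
#' @param traj The matching trajectory (same frame count).
#' @param path Output file or directory.
#' @param options List: `trace_len` (trailing trace frames, default 30),
#'   `marker_radius` (default 3).
#' @return `path`, invisibly.
#' @export
write_labeled_video <- function(seq, traj, path, options = list()) {
  pts <- as.data.frame(traj)
  if (nrow(pts) != n_frames(seq))
    stopf("write_labeled_video: trajectory length %d != frame count %d",
          nrow(pts), n_frames(seq))
  trace_len <- options$trace_len %||% 30
  mr <- options$marker_radius %||% 3
  d <- c(seq$working_size, 3)
  render <- function(i) {
    fr <- get_frame(seq, i)
    p <- pts[i, ]
    first <- max(1, i - trace_len)
    tr <- pts[first:i, ]
    tr <- tr[!is.na(tr$x), , drop = FALSE]
    if (nrow(tr) >= 2) {
      for (j in 2:nrow(tr))
        fr <- draw_segment(fr, tr$x[j - 1], tr$y[j - 1], tr$x[j], tr$y[j],
                           c(1, 1, 0.2), width = 1)
    }
    if (!is.na(p$box_x))
      fr <- draw_rect_outline(fr, bbox(p$box_x, p$box_y, p$box_w, p$box_h),
                              c(0.2, 0.8, 1))
    if (!is.na(p$x)) {
      fr <- draw_disc(fr, p$x, p$y, mr, status_color(p$status))
    } else {
      fr <- draw_rect_outline(fr, bbox(0, 0, d[2], d[1]), status_color("undetected"))
    }
    if (!is.na(p$p)) {
      len <- max(1, round(p$p * 60))
      fr[1:3, 1:len, 1] <- 1; fr[1:3, 1:len, 2] <- 0; fr[1:3, 1:len, 3] <- 0
    }
    fr
  }
  frames <- lapply(seq_len(n_frames(seq)), render)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    ok <- try(tiff::writeTIFF(frames, path, bits.per.sample = 8), silent = TRUE)
    if (inherits(ok, "try-error")) stopf("write_labeled_video: cannot write '%s'", path)
  } else {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stopf("write_labeled_video: cannot create '%s'", path)
    }
    for (i in seq_along(frames))
      png::writePNG(frames[[i]], file.path(path, sprintf("frame_%06d.png", i)))
  }
  yaml::write_yaml(list(fps = seq$fps), paste0(sub("/+$", "", path), ".yaml"))
  invisible(path)
}
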