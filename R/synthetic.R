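# Synthetic arena videos with exact ground truth.
#
# The generator emulates the three noise regimes the tracker is designed
# around: a high-contrast target in an open arena ("clean"), a target tethered
# by a wire-like distractor of similar intensity ("wire": the cable of a
# head-mounted recording), and a low-contrast target on a similar background
# ("lowcontrast": a white animal in a bright white box). Targets are
# anti-aliased ellipses rendered by 4x4 supersampled coverage so the analytic
# ellipse center is the exact ground-truth centroid.

#' Configure a synthetic arena scene
#'
#' @param regime One of `"clean"`, `"wire"`, `"lowcontrast"`, `"treadmill"`,
#'   `"two_animal"`; presets fill all fields below, which can be overridden.
#' @param n_frames Number of frames (default 300).
#' @param fps Frames per second (default 30).
#' @param size Working frame `(height, width)`; default `c(360, 640)`.
#' @param seed RNG seed; the whole video is deterministic given the seed.
#' @param ... Overrides for preset fields: `arena_color`, `wall_color`,
#'   `margin`, `gradient`, `targets` (list of targets, each with `axes`
#'   `(a, b)` semi-axes in px, `color`, optional `marker = list(color,
#'   radius)`, optional `start = c(x, y)` initial center (random when
#'   absent), optional `bounds`), `step_sd` (per-axis random-walk step SD in
#'   px), `band` (treadmill y half-width in px or NULL), `wire`
#'   (list `anchor`, `width`, `color`, `sag`, `sway`, or NULL), `hand`
#'   (list `interval`, `duration`, or NULL), `noise_sd` (per-pixel Gaussian
#'   SD on the `[0, 1]` scale), `label` (class label for annotations).
#' @return A `bhv_scene` configuration list.
#' @export
scene_config <- function(regime = c("clean", "wire", "lowcontrast", "treadmill",
                                    "two_animal"),
                         n_frames = 300, fps = 30, size = c(360, 640),
                         seed = 1, ...) {
  regime <- match.arg(regime)
  if (n_frames < 1) stopf("scene_config: n_frames must be >= 1")
  cfg <- list(
    regime = regime, n_frames = as.integer(n_frames), fps = fps,
    size = as.integer(size), seed = as.integer(seed),
    arena_color = c(0.75, 0.75, 0.75), wall_color = c(0.35, 0.35, 0.35),
    margin = 12, gradient = 0,
    targets = list(list(axes = c(a = 11, b = 8), color = c(0.12, 0.12, 0.12),
                        marker = NULL, bounds = NULL)),
    step_sd = c(2, 2), band = NULL, wire = NULL, hand = NULL,
    noise_sd = 2 / 255, label = "black_mouse"
  )
  if (regime == "wire") {
    cfg$wire <- list(anchor = NULL, width = 3, color = c(0.16, 0.16, 0.16),
                     sag = 50, sway = 40)
  } else if (regime == "lowcontrast") {
    # target/background luminance difference of 15/255
    cfg$targets[[1]]$color <- cfg$arena_color - 15 / 255
    cfg$gradient <- 0.08
    cfg$label <- "white_mouse"
  } else if (regime == "treadmill") {
    cfg$band <- 18
    cfg$step_sd <- c(3, 1)
  } else if (regime == "two_animal") {
    cfg$arena_color <- c(0.5, 0.5, 0.5)
    cfg$targets <- list(
      list(axes = c(a = 11, b = 8), color = c(0.88, 0.88, 0.86),
           marker = list(color = c(0.15, 0.25, 0.95), radius = 3.5),
           bounds = "left"),
      list(axes = c(a = 11, b = 8), color = c(0.88, 0.88, 0.86),
           marker = list(color = c(0.10, 0.80, 0.15), radius = 3.5),
           bounds = "right"))
    cfg$label <- "white_mouse"
  }
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  a_max <- max(vapply(cfg$targets, function(t) max(t$axes), numeric(1)))
  if (2 * a_max >= min(cfg$size) - 2 * cfg$margin)
    stopf("scene_config: target does not fit inside the arena")
  structure(cfg, class = "bhv_scene")
}

# Supersampled (4x4) coverage of an ellipse over its pixel window.
ellipse_coverage <- function(cx, cy, a, b, frame_size) {
  h <- frame_size[1]; w <- frame_size[2]
  xs <- max(0, floor(cx - a - 1)):min(w - 1, ceiling(cx + a + 1))
  ys <- max(0, floor(cy - b - 1)):min(h - 1, ceiling(cy + b + 1))
  off <- c(-0.375, -0.125, 0.125, 0.375)
  cov <- matrix(0, length(ys), length(xs))
  for (ox in off) for (oy in off) {
    gx <- outer(rep(1, length(ys)), xs + ox)
    gy <- outer(ys + oy, rep(1, length(xs)))
    cov <- cov + (((gx - cx) / a)^2 + ((gy - cy) / b)^2 <= 1)
  }
  list(xs = xs, ys = ys, cov = cov / 16)
}

blend_coverage <- function(frame, covr, color) {
  rows <- covr$ys + 1; cols <- covr$xs + 1
  for (ch in 1:3)
    frame[rows, cols, ch] <- frame[rows, cols, ch] * (1 - covr$cov) +
      color[ch] * covr$cov
  frame
}

# Tight box of the rendered support (pixels with any coverage).
coverage_box <- function(covr) {
  hit <- which(covr$cov > 0, arr.ind = TRUE)
  xs <- covr$xs[hit[, 2]]; ys <- covr$ys[hit[, 1]]
  c(x = min(xs), y = min(ys), w = max(xs) - min(xs) + 1, h = max(ys) - min(ys) + 1)
}

reflect_into <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

target_bounds <- function(cfg, tgt) {
  h <- cfg$size[1]; w <- cfg$size[2]
  a <- tgt$axes[["a"]]; b <- tgt$axes[["b"]]
  xlo <- cfg$margin + a + 1; xhi <- w - 1 - cfg$margin - a - 1
  ylo <- cfg$margin + b + 1; yhi <- h - 1 - cfg$margin - b - 1
  if (!is.null(cfg$band)) {
    ylo <- max(ylo, h / 2 - cfg$band); yhi <- min(yhi, h / 2 + cfg$band)
  }
  if (identical(tgt$bounds, "left")) xhi <- w / 2 - a - 4
  if (identical(tgt$bounds, "right")) xlo <- w / 2 + a + 4
  list(x = c(xlo, xhi), y = c(ylo, yhi))
}

render_background <- function(cfg) {
  h <- cfg$size[1]; w <- cfg$size[2]
  bg <- array(rep(cfg$wall_color, each = h * w), dim = c(h, w, 3))
  arena <- tracking_area(c(cfg$margin, cfg$margin,
                           w - 2 * cfg$margin, h - 2 * cfg$margin))
  m <- area_mask(arena, c(h, w))
  shade <- if (cfg$gradient > 0) {
    1 + cfg$gradient * (matrix(rep(0:(w - 1), each = h), h, w) / (w - 1) - 0.5)
  } else matrix(1, h, w)
  for (ch in 1:3) {
    plane <- bg[, , ch]
    plane[m] <- (cfg$arena_color[ch] * shade)[m]
    bg[, , ch] <- plane
  }
  list(bg = bg, arena = arena)
}

draw_wire <- function(frame, wire, from, to, phase) {
  p0 <- from
  p2 <- to
  # the cable bows towards the animal's side of the arena and keeps
  # swinging, as a real tether does, so its pixels stay dynamic rather
  # than being absorbed into a temporal-median background
  sway <- wire$sway * sin(2 * pi * phase / 120) + 0.8 * (p2[1] - p0[1])
  p1 <- c((p0[1] + p2[1]) / 2 + sway, (p0[2] + p2[2]) / 2 + wire$sag)
  t <- seq(0, 1, length.out = 150)
  bx <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1]
  by <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
  for (i in seq_along(t))
    frame <- draw_disc(frame, bx[i], by[i], wire$width / 2, wire$color)
  frame
}

#' Generate a synthetic arena video with exact ground truth
#'
#' Renders the configured scene: targets follow a bounded random walk with
#' reflecting walls (or a confined treadmill band), the wire regime adds a
#' swaying tether cable from a top-edge anchor to the target, the hand
#' distractor periodically pushes a large blob in from the left edge, and
#' per-pixel Gaussian noise is added and clipped. Ground truth records the
#' analytic ellipse center and the tight box of the rendered target support
#' for every frame and target.
#'
#' @param cfg A [scene_config()].
#' @return A list with elements `seq` (a [frame_sequence()]), `truth` (a
#'   `bhv_truth` data frame: frame, target, x, y, box_x, box_y, box_w,
#'   box_h), and `cfg`.
#' @export
generate_arena_video <- function(cfg) {
  stopifnot(inherits(cfg, "bhv_scene"))
  set.seed(cfg$seed)
  h <- cfg$size[1]; w <- cfg$size[2]
  scene <- render_background(cfg)
  n_t <- length(cfg$targets)
  pos <- lapply(cfg$targets, function(tgt) {
    b <- target_bounds(cfg, tgt)
    if (!is.null(tgt$start)) {
      c(clamp(tgt$start[1], b$x[1], b$x[2]), clamp(tgt$start[2], b$y[1], b$y[2]))
    } else {
      c(runif(1, b$x[1], b$x[2]), runif(1, b$y[1], b$y[2]))
    }
  })
  wire_anchor <- if (!is.null(cfg$wire))
    cfg$wire$anchor %||% c(w / 2, cfg$margin) else NULL
  frames <- vector("list", cfg$n_frames)
  truth <- vector("list", cfg$n_frames)
  for (f in seq_len(cfg$n_frames)) {
    fr <- scene$bg
    if (!is.null(cfg$wire))
      fr <- draw_wire(fr, cfg$wire, wire_anchor, pos[[1]], f)
    if (!is.null(cfg$hand)) {
      iv <- cfg$hand$interval %||% 180; du <- cfg$hand$duration %||% 6
      ph <- (f - 1) %% iv
      if (ph < du) {
        hx <- cfg$margin + 10 + 8 * ph
        hc <- ellipse_coverage(hx, h / 2, 35, 25, c(h, w))
        fr <- blend_coverage(fr, hc, c(0.2, 0.15, 0.12))
      }
    }
    rows <- vector("list", n_t)
    for (ti in seq_len(n_t)) {
      tgt <- cfg$targets[[ti]]
      covr <- ellipse_coverage(pos[[ti]][1], pos[[ti]][2],
                               tgt$axes[["a"]], tgt$axes[["b"]], c(h, w))
      fr <- blend_coverage(fr, covr, tgt$color)
      if (!is.null(tgt$marker)) {
        mc <- ellipse_coverage(pos[[ti]][1], pos[[ti]][2],
                               tgt$marker$radius, tgt$marker$radius, c(h, w))
        fr <- blend_coverage(fr, mc, tgt$marker$color)
      }
      box <- coverage_box(covr)
      rows[[ti]] <- data.frame(frame = f - 1L, target = ti,
                               x = pos[[ti]][1], y = pos[[ti]][2],
                               box_x = box[["x"]], box_y = box[["y"]],
                               box_w = box[["w"]], box_h = box[["h"]])
    }
    if (cfg$noise_sd > 0)
      fr <- clamp(fr + array(rnorm(length(fr), 0, cfg$noise_sd), dim = dim(fr)), 0, 1)
    frames[[f]] <- as_raw_frame(fr)
    truth[[f]] <- do.call(rbind, rows)
    for (ti in seq_len(n_t)) {
      b <- target_bounds(cfg, cfg$targets[[ti]])
      step <- rnorm(2, 0, cfg$step_sd)
      pos[[ti]] <- c(reflect_into(pos[[ti]][1] + step[1], b$x[1], b$x[2]),
                     reflect_into(pos[[ti]][2] + step[2], b$y[1], b$y[2]))
    }
  }
  truth <- do.call(rbind, truth)
  class(truth) <- c("bhv_truth", "data.frame")
  attr(truth, "source") <- "synthetic_generator"
  list(seq = frame_sequence(frames, fps = cfg$fps,
                            path = sprintf("synthetic:%s", cfg$regime)),
       truth = truth, cfg = cfg)
}

#' Sample a labeled training dataset from a synthetic scene
#'
#' Draws `n_images` frames evenly spread across a generated video (so poses
#' are diverse under the trajectory model) and attaches the generator's tight
#' true box as the annotation.
#'
#' @param cfg A [scene_config()].
#' @param n_images Number of labeled images (>= 1).
#' @return A list of [labeled_image()] objects, one annotated box per target.
#' @export
generate_labeled_dataset <- function(cfg, n_images) {
  if (n_images < 1) stopf("generate_labeled_dataset: n_images must be >= 1")
  if (cfg$n_frames < n_images) cfg$n_frames <- as.integer(n_images)
  vid <- generate_arena_video(cfg)
  idx <- unique(round(seq(1, n_frames(vid$seq), length.out = n_images)))
  stopifnot(length(idx) == n_images)
  lapply(idx, function(i) {
    tr <- vid$truth[vid$truth$frame == i - 1L, , drop = FALSE]
    boxes <- data.frame(x = tr$box_x, y = tr$box_y, w = tr$box_w, h = tr$box_h,
                        class = cfg$label)
    labeled_image(get_frame(vid$seq, i), boxes,
                  source = list(video = vid$seq$path, frame = i - 1L))
  })
}
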