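# The pluggable detection backend: a trainable single-scale convolutional
# detector, an oracle backend replaying (optionally perturbed) ground truth,
# a background-subtraction blob backend, and detector evaluation (AP@IoU).
#
# Detections are data frames with columns x, y, w, h (frame pixels, 0-based
# top-left origin), label, and confidence p in [0, 1], sorted by descending
# p.

empty_detections <- function() {
  data.frame(x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0),
             label = character(0), p = numeric(0))
}

#' Detector training configuration
#'
#' Defaults follow the reference protocol for this tracking approach:
#' mini-batch training with 16 images per optimizer step, 20 epochs,
#' learning rate 1e-4, and a 480-px normalized input resolution.
#' `input_size` must be a multiple of 32 so the 16-px-stride grid stays
#' whole at every downsampling stage.
#'
#' @param input_size Square network input side in pixels (default 480).
#' @param batch_size Images per optimizer step (default 16).
#' @param epochs Training epochs (default 20).
#' @param learning_rate Optimizer learning rate (default 1e-4).
#' @param optimizer `"sgdm"` (momentum SGD, the default) or `"adam"`. With
#'   the short fixed schedule, momentum SGD's gradient-proportional steps
#'   train from random weights far faster than Adam's bounded per-parameter
#'   steps.
#' @param momentum Momentum coefficient for `"sgdm"` (default 0.95).
#' @param n_anchors Number of box priors estimated by k-means over training
#'   box sizes (default 2).
#' @param anchors Optional explicit `n_anchors x 2` matrix of (w, h) priors
#'   in input pixels; overrides the k-means estimate.
#' @param loss_weights Named weights `(coord, obj, noobj, class)`; default
#'   `c(5, 1, 0.5, 1)`.
#' @param seed Seed for weight initialization, shuffling and anchor
#'   estimation.
#' @return A `bhv_traincfg` list.
#' @export
training_config <- function(input_size = 480, batch_size = 16, epochs = 20,
                            learning_rate = 1e-4,
                            optimizer = c("sgdm", "adam"), momentum = 0.95,
                            n_anchors = 2, anchors = NULL,
                            loss_weights = c(coord = 5, obj = 1, noobj = 0.5,
                                             class = 1),
                            seed = 1) {
  if (input_size %% 32 != 0 || input_size < 64)
    stopf("training_config: input_size must be a multiple of 32 (>= 64)")
  if (batch_size < 1 || epochs < 1 || learning_rate <= 0)
    stopf("training_config: batch_size/epochs must be >= 1, learning_rate > 0")
  if (!is.null(anchors) && any(anchors <= 0))
    stopf("training_config: anchors must be positive")
  optimizer <- match.arg(optimizer)
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = optimizer, momentum = momentum,
                 n_anchors = as.integer(n_anchors),
                 anchors = anchors, loss_weights = loss_weights,
                 seed = as.integer(seed)), class = "bhv_traincfg")
}

# --- letterboxing ---------------------------------------------------------

# Aspect-preserving resize onto a square gray canvas; the closed-form
# inverse maps network-space boxes back to frame coordinates.
letterbox_frame <- function(frame, input_size) {
  d <- dim(frame)
  scale <- min(input_size / d[1], input_size / d[2])
  nh <- round(d[1] * scale); nw <- round(d[2] * scale)
  resized <- resize_pixels(frame, c(nh, nw))
  canvas <- array(0.5, dim = c(input_size, input_size, 3))
  pad_y <- (input_size - nh) %/% 2L
  pad_x <- (input_size - nw) %/% 2L
  canvas[pad_y + seq_len(nh), pad_x + seq_len(nw), ] <- resized
  list(image = canvas, scale = scale, pad = c(x = pad_x, y = pad_y))
}

letterbox_box <- function(box, lb) {
  c(x = box[["x"]] * lb$scale + lb$pad[["x"]],
    y = box[["y"]] * lb$scale + lb$pad[["y"]],
    w = box[["w"]] * lb$scale, h = box[["h"]] * lb$scale)
}

unletterbox_box <- function(box, lb) {
  c(x = (box[["x"]] - lb$pad[["x"]]) / lb$scale,
    y = (box[["y"]] - lb$pad[["y"]]) / lb$scale,
    w = box[["w"]] / lb$scale, h = box[["h"]] / lb$scale)
}

# frame as (3, S*S) channel-major matrix for the network, centered at 0
frame_to_fmat <- function(frame) {
  d <- dim(frame)
  t(matrix(frame, d[1] * d[2], 3)) - 0.5
}

# --- training -------------------------------------------------------------

estimate_anchors <- function(wh, n_anchors) {
  wh <- wh[wh[, 1] > 0 & wh[, 2] > 0, , drop = FALSE]
  uq <- unique(round(wh, 4))
  if (nrow(uq) <= n_anchors) {
    ctr <- uq[rep(seq_len(nrow(uq)), length.out = n_anchors), , drop = FALSE]
    ctr <- ctr * (1 + 0.08 * (seq_len(n_anchors) - (n_anchors + 1) / 2))
    return(as.matrix(ctr))
  }
  km <- kmeans(wh, centers = n_anchors, nstart = 3, iter.max = 50)
  ctr <- km$centers[order(km$centers[, 1] * km$centers[, 2]), , drop = FALSE]
  as.matrix(ctr)
}

#' Train the convolutional detector
#'
#' Trains the compact single-scale detector on the training part of a
#' [split_dataset()] by mini-batch gradient descent with momentum
#' (`epochs * ceil(N / batch_size)` optimizer steps), logging per-epoch
#' training and validation loss. Anchors default to a seeded k-means over
#' the training box sizes. The run is deterministic given `cfg$seed` on a
#' fixed BLAS.
#'
#' @param split A `bhv_split`; every training image must carry at least one
#'   box.
#' @param cfg A [training_config()].
#' @param verbose Print per-epoch loss (default TRUE).
#' @return A `bhv_detector` (subclass `bhv_detector_cnn`) with a `history`
#'   element: `$steps` (one row per optimizer step: epoch, n_images, loss)
#'   and `$epochs` (train/validation loss).
#' @export
train_detector <- function(split, cfg = training_config(), verbose = TRUE) {
  train <- split$train
  if (length(train) == 0) stopf("train_detector: empty training set")
  nb <- vapply(train, function(im) nrow(im$boxes), integer(1))
  if (any(nb == 0)) stopf("train_detector: every training image needs >= 1 box")
  labels <- sort(unique(unlist(lapply(train, function(im) im$boxes$class))))
  C <- length(labels)
  S <- cfg$input_size
  G <- S %/% NET_STRIDE

  prep <- function(im) {
    px <- labeled_pixels(im)
    lb <- letterbox_frame(px, S)
    gt <- im$boxes
    rows <- lapply(seq_len(nrow(gt)), function(i) {
      b <- letterbox_box(c(x = gt$x[i], y = gt$y[i], w = gt$w[i], h = gt$h[i]), lb)
      data.frame(cx = b[["x"]] + b[["w"]] / 2, cy = b[["y"]] + b[["h"]] / 2,
                 w = b[["w"]], h = b[["h"]], class = match(gt$class[i], labels))
    })
    list(fmat = frame_to_fmat(lb$image), gt = do.call(rbind, rows))
  }
  tr <- lapply(train, prep)
  va <- lapply(split$validation, prep)

  anchors <- cfg$anchors
  if (is.null(anchors)) {
    wh <- do.call(rbind, lapply(tr, function(p) cbind(p$gt$w, p$gt$h)))
    anchors <- with_seed(cfg$seed, estimate_anchors(wh, cfg$n_anchors))
  }
  anchors <- matrix(as.numeric(anchors), ncol = 2)

  layers <- net_init(S, C, anchors, cfg$seed)
  ostate <- optim_init(layers)
  step_t <- 0L

  batch_pass <- function(items, update) {
    n <- length(items)
    fmat <- do.call(cbind, lapply(items, `[[`, "fmat"))
    fw <- net_forward(layers, fmat, S, n, keep_cache = update)
    ll <- yolo_loss(fw$out, n, fw$grid, S, anchors, C,
                    lapply(items, `[[`, "gt"), cfg$loss_weights)
    if (update) {
      grads <- net_backward(layers, fw$cache, ll$dZ, S, n)
      step_t <<- step_t + 1L
      st <- optim_step(layers, grads, ostate, cfg$learning_rate,
                       cfg$momentum, cfg$optimizer, step_t)
      layers <<- st$layers; ostate <<- st$state
    }
    ll$loss
  }

  steps <- list(); epoch_log <- list()
  n <- length(tr)
  set.seed(cfg$seed)
  step_i <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    ep_losses <- numeric(0)
    for (s0 in starts) {
      idx <- ord[s0:min(n, s0 + cfg$batch_size - 1)]
      loss <- batch_pass(tr[idx], update = TRUE)
      if (!is.finite(loss))
        stopf("train_detector: training diverged (non-finite loss) at epoch %d", ep)
      step_i <- step_i + 1L
      steps[[step_i]] <- data.frame(step = step_i, epoch = ep,
                                    n_images = length(idx), loss = loss)
      ep_losses <- c(ep_losses, loss / length(idx))
    }
    val_loss <- if (length(va) > 0) {
      vl <- 0
      for (s0 in seq(1, length(va), by = cfg$batch_size)) {
        idx <- s0:min(length(va), s0 + cfg$batch_size - 1)
        vl <- vl + batch_pass(va[idx], update = FALSE)
      }
      vl / length(va)
    } else NA_real_
    epoch_log[[ep]] <- data.frame(epoch = ep, train_loss = mean(ep_losses),
                                  val_loss = val_loss)
    if (verbose)
      message(sprintf("epoch %d/%d: train loss %.4f, val loss %s",
                      ep, cfg$epochs, mean(ep_losses),
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
  }
  structure(list(backend = "cnn", labels = labels, input_size = S,
                 weights = layers, anchors = anchors, cfg = cfg,
                 history = list(steps = do.call(rbind, steps),
                                epochs = do.call(rbind, epoch_log))),
            class = c("bhv_detector_cnn", "bhv_detector"))
}

#' @export
print.bhv_detector <- function(x, ...) {
  cat(sprintf("<bhv_detector:%s> labels {%s}, input %d px\n", x$backend,
              paste(x$labels, collapse = ", "), x$input_size %||% NA))
  if (!is.null(x$history))
    cat(sprintf("  trained %d steps, final train loss %.4f\n",
                nrow(x$history$steps), tail(x$history$epochs$train_loss, 1)))
  invisible(x)
}

# --- detection ------------------------------------------------------------

# Greedy non-maximum suppression per class label at IoU `thr`.
nms_detections <- function(dets, thr = 0.5) {
  if (nrow(dets) <= 1) return(dets)
  keep <- logical(nrow(dets))
  ord <- order(-dets$p)
  for (i in ord) {
    box_i <- c(x = dets$x[i], y = dets$y[i], w = dets$w[i], h = dets$h[i])
    dup <- FALSE
    for (j in which(keep)) {
      if (dets$label[j] != dets$label[i]) next
      if (bbox_iou(box_i, c(x = dets$x[j], y = dets$y[j], w = dets$w[j],
                            h = dets$h[j])) > thr) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  dets[keep, , drop = FALSE]
}

clamp_detections <- function(dets, frame_size) {
  if (nrow(dets) == 0) return(dets)
  keep <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    cl <- bbox_clamp(c(x = dets$x[i], y = dets$y[i], w = dets$w[i], h = dets$h[i]),
                     frame_size)
    if (!is.null(cl)) {
      dets$x[i] <- cl[["x"]]; dets$y[i] <- cl[["y"]]
      dets$w[i] <- cl[["w"]]; dets$h[i] <- cl[["h"]]
      keep[i] <- TRUE
    }
  }
  dets[keep, , drop = FALSE]
}

#' Run a detector on one frame
#'
#' Returns all detections with confidence `p >= threshold`, clamped into the
#' frame and sorted by descending `p`. The convolutional backend letterboxes
#' the frame to its input size, applies per-class non-maximum suppression at
#' IoU 0.5, and maps boxes back to frame coordinates; the default threshold
#' 0.25 is deliberately low, with box arbitration left to the tracker.
#'
#' @param d A `bhv_detector`.
#' @param frame `(h, w, 3)` numeric frame.
#' @param threshold Confidence threshold in `[0, 1]`.
#' @param frame_index 0-based frame index; required by the oracle backend
#'   and taken from the frame's `"frame_index"` attribute when absent.
#' @return A detections data frame (`x, y, w, h, label, p`); possibly empty.
#' @export
detect <- function(d, frame, threshold = 0.25, frame_index = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  UseMethod("detect")
}

#' @export
detect.bhv_detector_cnn <- function(d, frame, threshold = 0.25, frame_index = NULL) {
  lb <- letterbox_frame(frame, d$input_size)
  fw <- net_forward(d$weights, frame_to_fmat(lb$image), d$input_size, 1L)
  dets <- net_decode(fw$out, fw$grid, d$input_size, d$anchors, d$labels)
  if (nrow(dets) > 0) {
    for (i in seq_len(nrow(dets))) {
      b <- unletterbox_box(c(x = dets$x[i], y = dets$y[i], w = dets$w[i],
                             h = dets$h[i]), lb)
      dets$x[i] <- b[["x"]]; dets$y[i] <- b[["y"]]
      dets$w[i] <- b[["w"]]; dets$h[i] <- b[["h"]]
    }
    dets <- clamp_detections(dets, dim(frame)[1:2])
    dets <- nms_detections(dets, 0.5)
    dets <- dets[dets$p >= threshold, , drop = FALSE]
    dets <- dets[order(-dets$p), , drop = FALSE]
  }
  rownames(dets) <- NULL
  dets
}

#' Oracle detector backend from ground truth
#'
#' A test backend that replays the true boxes, optionally perturbed:
#' each box corner is shifted by an integer uniform jitter in
#' `[-jitter, jitter]`, whole frames are dropped with probability
#' `miss_rate`, and confidences are drawn uniformly in `[0.5, 1]`. The
#' perturbation is deterministic per `(frame index, seed)`, and the indices
#' of dropped frames are logged in the detector's `log` environment
#' (`d$log$missed`).
#'
#' @param truth A ground-truth table (e.g. from [generate_arena_video()])
#'   with columns `frame, box_x, box_y, box_w, box_h`.
#' @param jitter Max corner perturbation in pixels.
#' @param miss_rate Per-frame probability of returning no detections.
#' @param seed Seed for the per-frame RNG.
#' @return A `bhv_detector` (subclass `bhv_detector_oracle`).
#' @export
make_oracle_detector <- function(truth, jitter = 0, miss_rate = 0, seed = 1) {
  structure(list(backend = "oracle", truth = as.data.frame(truth),
                 labels = "target", jitter = jitter, miss_rate = miss_rate,
                 seed = seed, log = new.env(parent = emptyenv())),
            class = c("bhv_detector_oracle", "bhv_detector"))
}

#' @export
detect.bhv_detector_oracle <- function(d, frame, threshold = 0.25,
                                       frame_index = NULL) {
  frame_index <- frame_index %||% attr(frame, "frame_index")
  if (is.null(frame_index))
    stopf("oracle detector: frame_index is required")
  rows <- d$truth[d$truth$frame == frame_index, , drop = FALSE]
  if (nrow(rows) == 0)
    stopf("oracle detector: no ground truth for frame %d", frame_index)
  with_seed(derive_seed(d$seed, frame_index), {
    if (d$miss_rate > 0 && runif(1) < d$miss_rate) {
      d$log$missed <- c(d$log$missed, frame_index)
      empty_detections()
    } else {
    dets <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      x1 <- rows$box_x[i]; y1 <- rows$box_y[i]
      x2 <- x1 + rows$box_w[i]; y2 <- y1 + rows$box_h[i]
      if (d$jitter > 0) {
        j <- round(runif(4, -d$jitter, d$jitter))
        x1 <- x1 + j[1]; y1 <- y1 + j[2]; x2 <- x2 + j[3]; y2 <- y2 + j[4]
        if (x2 <= x1) x2 <- x1 + 1
        if (y2 <= y1) y2 <- y1 + 1
      }
      data.frame(x = x1, y = y1, w = x2 - x1, h = y2 - y1,
                 label = "target", p = runif(1, 0.5, 1))
    }))
    dets <- clamp_detections(dets, dim(frame)[1:2])
    dets <- dets[dets$p >= threshold, , drop = FALSE]
    dets[order(-dets$p), , drop = FALSE]
    }
  })
}

#' Replay detector backend
#'
#' Replays a fixed table of detections keyed by 0-based frame index —
#' useful for re-running analyses on saved detector output and for
#' constructing exactly known detection patterns in tests.
#'
#' @param detections Data frame with columns `frame, x, y, w, h, label, p`.
#' @return A `bhv_detector` (subclass `bhv_detector_replay`).
#' @export
make_replay_detector <- function(detections) {
  need <- c("frame", "x", "y", "w", "h", "label", "p")
  stopifnot(all(need %in% names(detections)))
  structure(list(backend = "replay", table = as.data.frame(detections),
                 labels = sort(unique(detections$label))),
            class = c("bhv_detector_replay", "bhv_detector"))
}

#' @export
detect.bhv_detector_replay <- function(d, frame, threshold = 0.25,
                                       frame_index = NULL) {
  frame_index <- frame_index %||% attr(frame, "frame_index")
  if (is.null(frame_index)) stopf("replay detector: frame_index is required")
  dets <- d$table[d$table$frame == frame_index,
                  c("x", "y", "w", "h", "label", "p"), drop = FALSE]
  dets <- dets[dets$p >= threshold, , drop = FALSE]
  dets <- dets[order(-dets$p), , drop = FALSE]
  rownames(dets) <- NULL
  dets
}

#' Blob detector backend (background subtraction only)
#'
#' A detector-shaped wrapper around whole-frame background subtraction: the
#' box of the largest foreground component, with confidence growing with
#' component size. Useful as a mock backend and for baseline comparisons.
#'
#' @param bg A [estimate_background()] model.
#' @param min_area Minimum component area (px) for a confident detection.
#' @param label Class label to report.
#' @return A `bhv_detector` (subclass `bhv_detector_blob`).
#' @export
make_blob_detector <- function(bg, min_area = 20, label = "target") {
  structure(list(backend = "blob", bg = bg, min_area = min_area,
                 labels = label),
            class = c("bhv_detector_blob", "bhv_detector"))
}

#' @export
detect.bhv_detector_blob <- function(d, frame, threshold = 0.25,
                                     frame_index = NULL) {
  dfr <- dim(frame)[1:2]
  fg <- subtract_foreground(frame, d$bg, bbox(0, 0, dfr[2], dfr[1]))
  if (fg$pixel_count == 0) return(empty_detections())
  px <- which(fg$component, arr.ind = TRUE)
  x1 <- min(px[, 2]) - 1; x2 <- max(px[, 2]) - 1
  y1 <- min(px[, 1]) - 1; y2 <- max(px[, 1]) - 1
  dets <- data.frame(x = x1, y = y1, w = x2 - x1 + 1, h = y2 - y1 + 1,
                     label = d$labels[1],
                     p = min(1, fg$pixel_count / (4 * d$min_area)))
  dets[dets$p >= threshold, , drop = FALSE]
}

# --- evaluation -----------------------------------------------------------

#' Evaluate a detector (average precision)
#'
#' AP at a fixed IoU threshold (default 0.5), computed by
#' descending-confidence greedy matching with one-to-one ground-truth
#' assignment and the interpolated precision envelope.
#'
#' @param d A `bhv_detector`.
#' @param test List of [labeled_image()] objects.
#' @param iou_threshold Match threshold (default 0.5).
#' @param detect_threshold Confidence floor used when collecting detections
#'   (default 0.01, i.e. evaluate nearly the full ranked list).
#' @return A list: `ap`, `n_images`, `n_gt`, and the precision/recall
#'   vectors of the ranked list.
#' @export
evaluate_detector <- function(d, test, iou_threshold = 0.5,
                              detect_threshold = 0.01) {
  if (length(test) == 0) stopf("evaluate_detector: empty test set")
  recs <- list()
  n_gt <- 0L
  for (i in seq_along(test)) {
    im <- test[[i]]
    gt <- im$boxes
    n_gt <- n_gt + nrow(gt)
    frame <- labeled_pixels(im)
    attr(frame, "frame_index") <- if (!is.null(im$source$frame)) im$source$frame else i - 1L
    dets <- detect(d, frame, threshold = detect_threshold)
    if (nrow(dets) == 0) next
    matched <- logical(nrow(gt))
    dets <- dets[order(-dets$p), , drop = FALSE]
    tp <- logical(nrow(dets))
    for (k in seq_len(nrow(dets))) {
      ious <- vapply(seq_len(nrow(gt)), function(g)
        if (matched[g] || gt$class[g] != dets$label[k]) -1 else
          bbox_iou(c(x = dets$x[k], y = dets$y[k], w = dets$w[k], h = dets$h[k]),
                   c(x = gt$x[g], y = gt$y[g], w = gt$w[g], h = gt$h[g])),
        numeric(1))
      if (length(ious) && max(ious) >= iou_threshold) {
        matched[which.max(ious)] <- TRUE
        tp[k] <- TRUE
      }
    }
    recs[[length(recs) + 1]] <- data.frame(p = dets$p, tp = tp)
  }
  if (length(recs) == 0 || n_gt == 0)
    return(list(ap = 0, n_images = length(test), n_gt = n_gt,
                precision = numeric(0), recall = numeric(0)))
  all <- do.call(rbind, recs)
  all <- all[order(-all$p), , drop = FALSE]
  tp_cum <- cumsum(all$tp)
  fp_cum <- cumsum(!all$tp)
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # interpolated precision envelope, integrated over recall steps
  penv <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * penv)
  list(ap = ap, n_images = length(test), n_gt = n_gt,
       precision = precision, recall = recall)
}
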