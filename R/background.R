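# Background model estimation, foreground extraction inside a region of
# interest, and connected-component centroid computation.
#
# The animal's position is the centroid of the largest foreground component
# obtained by pixel-by-pixel comparison of the current frame with a
# reference background image.  Differencing happens on Rec. 601 luminance so
# Otsu thresholding stays well-defined; the difference is signed by a
# polarity switch because both dark-on-light (black mice) and light-on-dark
# (white mice) targets occur.

#' Estimate a background model
#'
#' The default temporal-median method samples `k` frames uniformly across
#' the sequence and takes the per-pixel, per-channel median: a pixel keeps
#' the arena color as long as the moving animal occupies it in fewer than
#' half of the sampled frames. An empty-arena reference frame, when
#' available, is the preferred alternative (`method = "supplied"`).
#'
#' @param seq A [frame_sequence()] (ignored for `"supplied"` with a
#'   reference).
#' @param method `"temporal_median"` or `"supplied"`.
#' @param k Number of frames sampled for the median (>= 3; default 25).
#' @param reference Reference frame for `"supplied"`.
#' @param polarity `"target_darker"`, `"target_lighter"`, or `"either"`.
#' @param threshold `"otsu"` (parameter-free, per-ROI) or a fixed numeric
#'   threshold on the 0–255 difference scale.
#' @param morphology Side of the square opening kernel in pixels (default 3;
#'   0 disables opening).
#' @return An object of class `bhv_background`.
#' @export
estimate_background <- function(seq, method = c("temporal_median", "supplied"),
                                k = 25, reference = NULL,
                                polarity = c("target_darker", "target_lighter",
                                             "either"),
                                threshold = "otsu", morphology = 3) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  if (is.numeric(threshold) && (threshold <= 0 || threshold >= 255))
    stopf("estimate_background: fixed threshold must lie in (0, 255)")
  if (method == "supplied") {
    if (is.null(reference)) stopf("estimate_background: reference frame required")
    ref <- reference
  } else {
    if (k < 3) stopf("estimate_background: k must be >= 3")
    n <- n_frames(seq)
    if (n < k) stopf("estimate_background: sequence has %d < k = %d frames", n, k)
    idx <- round(seq.int(1, n, length.out = k))
    d <- c(seq$working_size, 3)
    stack <- vapply(idx, function(i) as.numeric(get_frame(seq, i)),
                    numeric(prod(d)))
    ref <- array(cpp_row_median(stack), dim = d)
  }
  structure(list(reference = ref, polarity = polarity,
                 threshold_policy = threshold, morphology = morphology),
            class = "bhv_background")
}

#' @export
print.bhv_background <- function(x, ...) {
  thr <- if (is.numeric(x$threshold_policy))
    sprintf("fixed(%g)", x$threshold_policy) else x$threshold_policy
  cat(sprintf("<bhv_background> %dx%d reference, polarity %s, threshold %s, opening %dpx\n",
              dim(x$reference)[1], dim(x$reference)[2], x$polarity, thr,
              x$morphology))
  invisible(x)
}

#' Save / load a background model (image + YAML sidecar)
#' @param bg A `bhv_background`.
#' @param path PNG path for the reference image; policy goes to
#'   `<path>.yaml`.
#' @return `path` invisibly, or the restored model.
#' @export
write_background <- function(bg, path) {
  png::writePNG(bg$reference, path)
  yaml::write_yaml(list(polarity = bg$polarity,
                        threshold = bg$threshold_policy,
                        morphology = bg$morphology), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  thr <- meta$threshold
  if (is.character(thr) && thr != "otsu") thr <- as.numeric(thr)
  estimate_background(NULL, method = "supplied",
                      reference = normalize_channels(png::readPNG(path)),
                      polarity = meta$polarity, threshold = thr,
                      morphology = meta$morphology)
}

#' Extract foreground inside a region of interest
#'
#' Computes the signed luminance difference between the frame and the
#' background reference inside `roi`, thresholds it (Otsu on the in-ROI
#' difference histogram, or a fixed value), applies a morphological opening
#' (removing speckle and wire-thin structures), keeps the largest
#' 8-connected component, and returns its pixel-mean centroid in frame
#' coordinates. Ties in component area are broken by the topmost, then
#' leftmost bounding pixel.
#'
#' @param frame `(h, w, 3)` numeric frame.
#' @param bg A [estimate_background()] model.
#' @param roi Bounding box `c(x, y, w, h)`; clamped into the frame.
#' @return A `bhv_foreground` list: `mask` (logical, ROI-sized), `component`
#'   (logical mask of the kept component), `centroid` (`c(x, y)` or NULL),
#'   `pixel_count`, `roi`.
#' @export
subtract_foreground <- function(frame, bg, roi) {
  d <- dim(frame)
  roi <- bbox_clamp(bbox_round_out(roi), d[1:2])
  if (is.null(roi) || roi[["w"]] < 1 || roi[["h"]] < 1)
    stopf("subtract_foreground: ROI has no area inside the frame")
  rows <- roi[["y"]] + seq_len(roi[["h"]])
  cols <- roi[["x"]] + seq_len(roi[["w"]])
  lf <- luminance(frame[rows, cols, , drop = FALSE])
  lb <- luminance(bg$reference[rows, cols, , drop = FALSE])
  diff <- switch(bg$polarity,
                 target_darker = pmax(lb - lf, 0),
                 target_lighter = pmax(lf - lb, 0),
                 either = abs(lf - lb))
  thr <- if (is.numeric(bg$threshold_policy)) bg$threshold_policy / 255
         else EBImage::otsu(EBImage::Image(diff), range = c(0, 1))
  mask <- diff > max(thr, 1e-6)
  if (bg$morphology >= 2 && any(mask)) {
    opened <- EBImage::opening(EBImage::Image(mask * 1),
                               EBImage::makeBrush(bg$morphology, "box"))
    mask <- EBImage::imageData(opened) > 0.5
  }
  if (!any(mask)) {
    return(structure(list(mask = mask, component = mask, centroid = NULL,
                          pixel_count = 0L, roi = roi),
                     class = "bhv_foreground"))
  }
  lab <- cpp_label8(mask)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # deterministic tie-break: topmost, then leftmost bounding pixel
    key <- vapply(best, function(l) {
      px <- which(lab == l, arr.ind = TRUE)
      min(px[, 1]) * (roi[["w"]] + 1) + min(px[, 2])
    }, numeric(1))
    best <- best[which.min(key)]
  }
  comp <- lab == best
  ctr <- centroid_of_mask(comp, offset = c(roi[["x"]], roi[["y"]]))
  structure(list(mask = mask, component = comp, centroid = ctr,
                 pixel_count = sum(comp), roi = roi),
            class = "bhv_foreground")
}

#' Centroid of a binary mask
#'
#' Arithmetic mean of the set pixels' 0-based `(x, y)` coordinates plus an
#' offset, returned at sub-pixel precision. Raises an error on an empty
#' mask so that callers must use an explicit fallback rather than a silent
#' zero.
#'
#' @param mask Logical matrix.
#' @param offset `(x, y)` added to the mask-local coordinates (e.g. the ROI
#'   corner).
#' @return `c(x, y)` numeric.
#' @export
centroid_of_mask <- function(mask, offset = c(0, 0)) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0) stopf("centroid_of_mask: empty mask")
  c(x = offset[1] + mean(px[, 2] - 1), y = offset[2] + mean(px[, 1] - 1))
}
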