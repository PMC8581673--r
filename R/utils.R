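# Shared helpers: coordinate conventions and small numeric utilities.
#
# All pixel coordinates in the package are 0-based with the origin at the
# top-left corner, x increasing rightwards and y downwards.  A pixel's
# integer coordinate is its center.  Bounding boxes are (x, y, w, h) with
# half-open extent [x, x + w) x [y, y + h): a box covers pixels
# x .. x + w - 1 horizontally.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Construct a bounding box
#'
#' Boxes are named numeric vectors `c(x, y, w, h)` in the package-wide
#' 0-based, top-left-origin pixel convention with half-open extent.
#'
#' @param x,y Top-left corner (pixels, 0-based).
#' @param w,h Width and height in pixels; must be positive.
#' @return A named numeric vector of length 4.
#' @export
bbox <- function(x, y, w, h) {
  if (any(!is.finite(c(x, y, w, h)))) stopf("bbox: non-finite coordinates")
  if (w <= 0 || h <= 0) stopf("bbox: width and height must be positive")
  c(x = as.numeric(x), y = as.numeric(y), w = as.numeric(w), h = as.numeric(h))
}

# Round a (possibly fractional) box outward to integer corners.
bbox_round_out <- function(box) {
  x1 <- floor(box[["x"]]); y1 <- floor(box[["y"]])
  x2 <- ceiling(box[["x"]] + box[["w"]]); y2 <- ceiling(box[["y"]] + box[["h"]])
  c(x = x1, y = y1, w = x2 - x1, h = y2 - y1)
}

# Clamp a box into a frame of size (h, w); returns NULL if nothing remains.
bbox_clamp <- function(box, frame_size) {
  h <- frame_size[1]; w <- frame_size[2]
  x1 <- max(0, box[["x"]]); y1 <- max(0, box[["y"]])
  x2 <- min(w, box[["x"]] + box[["w"]]); y2 <- min(h, box[["y"]] + box[["h"]])
  if (x2 <= x1 || y2 <= y1) return(NULL)
  c(x = x1, y = y1, w = x2 - x1, h = y2 - y1)
}

#' Intersection-over-union of two boxes
#'
#' @param a,b Boxes as `c(x, y, w, h)`.
#' @return IoU in \[0, 1\].
#' @export
bbox_iou <- function(a, b) {
  ix <- max(0, min(a[["x"]] + a[["w"]], b[["x"]] + b[["w"]]) - max(a[["x"]], b[["x"]]))
  iy <- max(0, min(a[["y"]] + a[["h"]], b[["y"]] + b[["h"]]) - max(a[["y"]], b[["y"]]))
  inter <- ix * iy
  un <- a[["w"]] * a[["h"]] + b[["w"]] * b[["h"]] - inter
  if (un <= 0) return(0)
  inter / un
}

# Rec. 601 luma of an (h, w, 3) frame in [0, 1]; returns an (h, w) matrix.
luminance <- function(frame) {
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# RGB frame -> HSV array (h, w, 3); hue in [0, 1).
frame_to_hsv <- function(frame) {
  d <- dim(frame)
  m <- rgb2hsv(t(matrix(frame, d[1] * d[2], 3)), maxColorValue = 1)
  array(t(m), dim = d)
}

# Bilinear resize of an (h, w) matrix or (h, w, 3) array to target (h, w).
resize_pixels <- function(x, target) {
  d <- dim(x)
  if (d[1] == target[1] && d[2] == target[2]) return(x)
  if (length(d) == 2) {
    img <- EBImage::Image(t(x))
    out <- EBImage::imageData(EBImage::resize(img, w = target[2], h = target[1]))
    return(t(out))
  }
  img <- EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::imageData(EBImage::resize(img, w = target[2], h = target[1]))
  aperm(out, c(2, 1, 3))
}

# Deterministic per-event sub-seed derived from a user seed (kept < 2^31).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 1000003) %% 2147483647)
}

# Run code under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
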