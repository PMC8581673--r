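# Training-data curation: keyframe extraction, annotation I/O, the
# 70/10/20 split, and the augmentation / resizing applied before detector
# training.

#' Construct a labeled image
#'
#' @param image `(h, w, 3)` numeric array in `[0, 1]` (or raw 8-bit array).
#' @param boxes Data frame with columns `x, y, w, h, class`; boxes are
#'   clamped into the image.
#' @param source Optional list `(video, frame)` recording provenance.
#' @return An object of class `bhv_labeled`.
#' @export
labeled_image <- function(image, boxes, source = NULL) {
  image <- as_raw_frame(image)
  d <- dim(image)
  boxes <- as.data.frame(boxes)
  need <- c("x", "y", "w", "h", "class")
  if (!all(need %in% names(boxes)))
    stopf("labeled_image: boxes need columns %s", paste(need, collapse = ", "))
  for (i in seq_len(nrow(boxes))) {
    cl <- bbox_clamp(c(x = boxes$x[i], y = boxes$y[i], w = boxes$w[i], h = boxes$h[i]),
                     d[1:2])
    if (is.null(cl)) stopf("labeled_image: box %d lies outside the image", i)
    boxes$x[i] <- cl[["x"]]; boxes$y[i] <- cl[["y"]]
    boxes$w[i] <- cl[["w"]]; boxes$h[i] <- cl[["h"]]
  }
  structure(list(image = image, boxes = boxes, source = source),
            class = "bhv_labeled")
}

# numeric [0,1] view of the stored image
labeled_pixels <- function(item) {
  array(as.integer(item$image) / 255, dim = dim(item$image))
}

# 36 x 64 grayscale thumbnail, flattened; the K-means feature vector.
frame_feature <- function(frame) {
  as.numeric(resize_pixels(luminance(frame), c(36, 64)))
}

#' Extract frames from videos for labeling
#'
#' Random mode samples `n` frames uniformly without replacement from the
#' pooled videos. K-means mode clusters downscaled grayscale thumbnails into
#' `n` clusters and returns, for each cluster, the frame closest to its
#' center — a cheap diverse-pose selection for building a labeling set
#' (e.g. 300 keyframes pooled from six videos). Both modes are deterministic
#' given `seed`.
#'
#' @param videos A [frame_sequence()] or list of them.
#' @param n Number of frames to extract.
#' @param mode `"random"` or `"kmeans"`.
#' @param seed RNG seed.
#' @return List of records `list(image, video, frame)` with 0-based frame
#'   indices.
#' @export
extract_frames <- function(videos, n, mode = c("random", "kmeans"), seed = 1) {
  mode <- match.arg(mode)
  if (inherits(videos, "bhv_frames")) videos <- list(videos)
  counts <- vapply(videos, n_frames, integer(1))
  total <- sum(counts)
  if (n < 1) stopf("extract_frames: n must be >= 1")
  if (n > total) stopf("extract_frames: n = %d exceeds the %d available frames", n, total)
  pool <- data.frame(video = rep(seq_along(videos), counts),
                     frame = unlist(lapply(counts, seq_len)))
  pick <- with_seed(seed, {
    if (mode == "random") {
      sort(sample.int(total, n))
    } else {
      feats <- do.call(rbind, lapply(seq_len(total), function(i)
        frame_feature(get_frame(videos[[pool$video[i]]], pool$frame[i]))))
      kmeans_representatives(feats, n)
    }
  })
  lapply(pick, function(i) {
    list(image = get_frame(videos[[pool$video[i]]], pool$frame[i]),
         video = pool$video[i], frame = pool$frame[i] - 1L)
  })
}

# K-means over unique feature rows (duplicated static frames would otherwise
# abort stats::kmeans); each cluster contributes the frame nearest its
# center, ties broken by lowest frame index.  If there are fewer distinct
# appearances than clusters the remainder is filled by seeded random draws.
kmeans_representatives <- function(feats, n) {
  uq <- unique(feats)
  k <- min(n, nrow(uq))
  centers <- if (k == nrow(uq)) uq else kmeans(uq, centers = k, nstart = 1,
                                               iter.max = 50)$centers
  reps <- integer(k)
  for (ci in seq_len(k)) {
    d2 <- rowSums((feats - matrix(centers[ci, ], nrow(feats), ncol(feats),
                                  byrow = TRUE))^2)
    reps[ci] <- which.min(d2)
  }
  reps <- unique(reps)
  if (length(reps) < n) {
    rest <- setdiff(seq_len(nrow(feats)), reps)
    reps <- c(reps, sample(rest, n - length(reps)))
  }
  sort(reps[seq_len(n)])
}

#' Split a labeled dataset into train / validation / test
#'
#' Realized sizes follow round-half-up of `N * fraction` for the validation
#' and test parts, with the remainder (including rounding slack) assigned to
#' the training part; the default fractions are 70/10/20. The partition is a
#' seeded random shuffle — disjoint and exhaustive.
#'
#' @param images List of [labeled_image()] objects (>= 3).
#' @param fractions `(train, validation, test)` summing to 1.
#' @param seed RNG seed.
#' @return An object of class `bhv_split` with elements `train`,
#'   `validation`, `test`, `fractions`, `seed`.
#' @export
split_dataset <- function(images, fractions = c(0.7, 0.1, 0.2), seed = 1) {
  if (length(images) < 3) stopf("split_dataset: need at least 3 images")
  if (abs(sum(fractions) - 1) > 1e-9)
    stopf("split_dataset: fractions must sum to 1")
  n <- length(images)
  rhu <- function(x) floor(x + 0.5)
  n_val <- rhu(n * fractions[2])
  n_test <- rhu(n * fractions[3])
  n_train <- n - n_val - n_test
  if (n_train < 0) stopf("split_dataset: fractions leave no training images")
  ord <- with_seed(seed, sample.int(n))
  structure(list(
    train = images[ord[seq_len(n_train)]],
    validation = images[ord[n_train + seq_len(n_val)]],
    test = images[ord[n_train + n_val + seq_len(n_test)]],
    fractions = fractions, seed = seed
  ), class = "bhv_split")
}

#' @export
print.bhv_split <- function(x, ...) {
  cat(sprintf("<bhv_split> train %d / validation %d / test %d (fractions %s, seed %d)\n",
              length(x$train), length(x$validation), length(x$test),
              paste(x$fractions, collapse = "/"), x$seed))
  invisible(x)
}

#' Augmentation configuration
#'
#' Color distortion (HSV jitter) and information dropping (rectangular
#' zero-patches), plus an optional horizontal flip. The patch count and size
#' ranges are declared defaults; a patch that would fully cover a labeled
#' box is re-sampled up to 10 times and then skipped, since erasing the whole
#' target would corrupt supervision.
#'
#' @param hue_jitter Max absolute hue shift (fraction of the hue circle).
#' @param sat_jitter,val_jitter Max relative saturation / brightness change.
#' @param dropout_count Integer range `c(lo, hi)` of patches per image.
#' @param dropout_frac Patch side as a fraction range of the shorter image
#'   side.
#' @param flip_prob Probability of a horizontal flip.
#' @param seed Optional seed consumed by [augment()].
#' @return An `bhv_augcfg` list.
#' @export
augmentation_config <- function(hue_jitter = 0.05, sat_jitter = 0.2,
                                val_jitter = 0.2, dropout_count = c(0, 3),
                                dropout_frac = c(0.05, 0.20), flip_prob = 0.5,
                                seed = NULL) {
  stopifnot(all(is.finite(c(hue_jitter, sat_jitter, val_jitter,
                            dropout_count, dropout_frac))),
            flip_prob >= 0, flip_prob <= 1)
  structure(list(hue_jitter = hue_jitter, sat_jitter = sat_jitter,
                 val_jitter = val_jitter, dropout_count = dropout_count,
                 dropout_frac = dropout_frac, flip_prob = flip_prob,
                 seed = seed), class = "bhv_augcfg")
}

#' Augment a labeled image
#'
#' HSV color jitter and dropout patches leave the boxes untouched; a
#' horizontal flip mirrors box x-coordinates (`x' = W - x - w`). Degenerate
#' ranges (all-zero jitter, zero patches, flip probability 0) reproduce the
#' input exactly. Deterministic given `seed`.
#'
#' @param item A [labeled_image()].
#' @param cfg An [augmentation_config()].
#' @param seed RNG seed; defaults to `cfg$seed` (NULL uses the current RNG
#'   stream).
#' @return The augmented [labeled_image()].
#' @export
augment <- function(item, cfg = augmentation_config(), seed = cfg$seed) {
  img <- labeled_pixels(item)
  boxes <- item$boxes
  d <- dim(img)
  with_seed(seed, {
    identity_color <- cfg$hue_jitter == 0 && cfg$sat_jitter == 0 && cfg$val_jitter == 0
    if (!identity_color) {
      hsv <- frame_to_hsv(img)
      hsv[, , 1] <- (hsv[, , 1] + runif(1, -cfg$hue_jitter, cfg$hue_jitter)) %% 1
      hsv[, , 2] <- clamp(hsv[, , 2] * (1 + runif(1, -cfg$sat_jitter, cfg$sat_jitter)), 0, 1)
      hsv[, , 3] <- clamp(hsv[, , 3] * (1 + runif(1, -cfg$val_jitter, cfg$val_jitter)), 0, 1)
      m <- grDevices::hsv(hsv[, , 1], hsv[, , 2], hsv[, , 3])
      rgbm <- grDevices::col2rgb(m) / 255
      img <- array(t(rgbm), dim = d)
    }
    n_patch <- if (cfg$dropout_count[2] > 0)
      sample(cfg$dropout_count[1]:cfg$dropout_count[2], 1) else 0
    if (n_patch > 0) {
      side_rng <- round(cfg$dropout_frac * min(d[1:2]))
      for (i in seq_len(n_patch)) {
        for (attempt in 1:10) {
          side <- max(1, round(runif(1, side_rng[1], side_rng[2])))
          px <- sample.int(d[2] - side + 1, 1) - 1
          py <- sample.int(d[1] - side + 1, 1) - 1
          covers <- any(boxes$x >= px & boxes$y >= py &
                        boxes$x + boxes$w <= px + side &
                        boxes$y + boxes$h <= py + side)
          if (!covers) {
            img[py + seq_len(side), px + seq_len(side), ] <- 0
            break
          }
        }
      }
    }
    if (cfg$flip_prob > 0 && runif(1) < cfg$flip_prob) {
      img <- img[, d[2]:1, , drop = FALSE]
      boxes$x <- d[2] - boxes$x - boxes$w
    }
  })
  labeled_image(img, boxes, source = item$source)
}

#' Resize a labeled image together with its boxes
#'
#' The image is bilinearly resized; each box is scaled by the same per-axis
#' factors, rounded, and clamped, preserving the relative box center to
#' within a pixel.
#'
#' @param item A [labeled_image()].
#' @param target `(height, width)` in pixels.
#' @return The resized [labeled_image()].
#' @export
resize_with_boxes <- function(item, target) {
  if (any(target < 1)) stopf("resize_with_boxes: target must be positive")
  d <- dim(item$image)
  if (d[1] == target[1] && d[2] == target[2]) return(item)
  img <- resize_pixels(labeled_pixels(item), target)
  sy <- target[1] / d[1]; sx <- target[2] / d[2]
  boxes <- item$boxes
  x2 <- (boxes$x + boxes$w) * sx; y2 <- (boxes$y + boxes$h) * sy
  boxes$x <- round(boxes$x * sx); boxes$y <- round(boxes$y * sy)
  boxes$w <- pmax(1, round(x2) - boxes$x); boxes$h <- pmax(1, round(y2) - boxes$y)
  labeled_image(img, boxes, source = item$source)
}

#' Read and write annotation tables
#'
#' Two dialects round-trip losslessly: a flat CSV with columns
#' `video, frame, x, y, w, h, class` and a COCO-style JSON with `images`,
#' `annotations` (bbox as `[x, y, w, h]`), and `categories`. Unknown CSV
#' columns are preserved on read and dropped with a warning on write.
#'
#' @param path File path; format inferred from the extension (`.csv` /
#'   `.json`) unless `format` is given.
#' @param format `"auto"`, `"csv"` or `"coco"`.
#' @return `read_annotations` returns a data frame of box references;
#'   `write_annotations` returns `path` invisibly.
#' @export
read_annotations <- function(path, format = c("auto", "csv", "coco")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "json") "coco" else "csv"
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("video", "frame", "x", "y", "w", "h", "class")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stopf("read_annotations: missing columns: %s", paste(miss, collapse = ", "))
    bad <- which(!is.finite(df$w) | !is.finite(df$h) | df$w <= 0 | df$h <= 0)
    if (length(bad))
      stopf("read_annotations: invalid box on line %d of '%s'", bad[1] + 1L, path)
    return(df)
  }
  cc <- jsonlite::read_json(path, simplifyVector = FALSE)
  imgs <- do.call(rbind, lapply(cc$images, function(im)
    data.frame(id = im$id, video = im$video %||% im$file_name,
               frame = im$frame %||% 0L)))
  cats <- vapply(cc$categories, function(ct) ct$name, character(1))
  names(cats) <- vapply(cc$categories, function(ct) as.character(ct$id), character(1))
  rows <- lapply(seq_along(cc$annotations), function(i) {
    an <- cc$annotations[[i]]
    bb <- unlist(an$bbox)
    if (length(bb) != 4 || bb[3] <= 0 || bb[4] <= 0)
      stopf("read_annotations: invalid bbox in annotation %d of '%s'", i, path)
    im <- imgs[imgs$id == an$image_id, , drop = FALSE]
    if (nrow(im) != 1)
      stopf("read_annotations: annotation %d references unknown image id", i)
    data.frame(video = im$video, frame = im$frame, x = bb[1], y = bb[2],
               w = bb[3], h = bb[4], class = cats[[as.character(an$category_id)]])
  })
  do.call(rbind, rows)
}

#' @rdname read_annotations
#' @param annotations Data frame with columns `video, frame, x, y, w, h,
#'   class` (extra columns are dropped with a warning).
#' @export
write_annotations <- function(annotations, path, format = c("auto", "csv", "coco")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "json") "coco" else "csv"
  need <- c("video", "frame", "x", "y", "w", "h", "class")
  extra <- setdiff(names(annotations), need)
  if (length(extra)) {
    warning("write_annotations: dropping unknown columns: ",
            paste(extra, collapse = ", "))
    annotations <- annotations[need]
  }
  if (format == "csv") {
    write.csv(annotations[need], path, row.names = FALSE)
    return(invisible(path))
  }
  key <- paste(annotations$video, annotations$frame, sep = "\r")
  ukey <- unique(key)
  img_id <- match(key, ukey)
  images <- lapply(seq_along(ukey), function(i) {
    r <- annotations[match(ukey[i], key), ]
    list(id = i, file_name = sprintf("%s_%06d.png", r$video, r$frame),
         video = r$video, frame = r$frame)
  })
  classes <- sort(unique(annotations$class))
  categories <- lapply(seq_along(classes), function(i)
    list(id = i, name = classes[i]))
  anns <- lapply(seq_len(nrow(annotations)), function(i)
    list(id = i, image_id = img_id[i],
         bbox = c(annotations$x[i], annotations$y[i],
                  annotations$w[i], annotations$h[i]),
         category_id = match(annotations$class[i], classes)))
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = categories),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
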