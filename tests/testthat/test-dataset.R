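# Frame extraction, dataset splitting, augmentation, annotation I/O.

test_that("random extraction is exhaustive at n = N and reproducible", {
  vid <- fx_clean()
  n <- n_frames(vid$seq)
  all1 <- extract_frames(vid$seq, n, mode = "random", seed = 9)
  expect_length(all1, n)
  expect_setequal(vapply(all1, `[[`, integer(1), "frame"), 0:(n - 1))
  some1 <- extract_frames(vid$seq, 7, mode = "random", seed = 10)
  some2 <- extract_frames(vid$seq, 7, mode = "random", seed = 10)
  expect_identical(vapply(some1, `[[`, integer(1), "frame"),
                   vapply(some2, `[[`, integer(1), "frame"))
  expect_error(extract_frames(vid$seq, n + 1), "exceeds")
})

test_that("k-means extraction picks one frame per distinct appearance", {
  dark_left <- array(0.8, dim = c(36, 64, 3)); dark_left[, 1:32, ] <- 0.1
  dark_right <- array(0.8, dim = c(36, 64, 3)); dark_right[, 33:64, ] <- 0.1
  v1 <- frame_sequence(rep(list(dark_left), 5), fps = 30)
  v2 <- frame_sequence(rep(list(dark_right), 5), fps = 30)
  picks <- extract_frames(list(v1, v2), 2, mode = "kmeans", seed = 1)
  expect_setequal(vapply(picks, `[[`, integer(1), "video"), c(1L, 2L))
  again <- extract_frames(list(v1, v2), 2, mode = "kmeans", seed = 1)
  expect_identical(vapply(picks, function(p) p$video * 100L + p$frame, integer(1)),
                   vapply(again, function(p) p$video * 100L + p$frame, integer(1)))
})

test_that("splits follow the rounding rule and are disjoint and exhaustive", {
  pool <- fx_pool()
  # degenerate fractions
  sp <- split_dataset(pool[1:10], c(1, 0, 0), seed = 1)
  expect_length(sp$train, 10)
  expect_length(sp$validation, 0)
  # hand-recomputed rounding rule across sizes, incl. the 301-image case
  rhu <- function(x) floor(x + 0.5)
  set.seed(20)
  sizes <- c(3, 7, 10, 301, sample(3:1000, 6))
  for (n in sizes) {
    imgs <- rep(pool[1:3], length.out = n)
    sp <- split_dataset(imgs, c(0.7, 0.1, 0.2), seed = n)
    expect_length(sp$validation, rhu(n * 0.1))
    expect_length(sp$test, rhu(n * 0.2))
    expect_length(sp$train, n - rhu(n * 0.1) - rhu(n * 0.2))
  }
  # disjoint + exhaustive on tagged copies
  tagged <- lapply(seq_len(40), function(i) {
    im <- pool[[1 + i %% length(pool)]]; im$source$frame <- i; im
  })
  sp <- split_dataset(tagged, seed = 3)
  ids <- c(vapply(sp$train, function(x) x$source$frame, numeric(1)),
           vapply(sp$validation, function(x) x$source$frame, numeric(1)),
           vapply(sp$test, function(x) x$source$frame, numeric(1)))
  expect_setequal(ids, 1:40)
  expect_error(split_dataset(tagged, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("augmentation: identity config, flip arithmetic, dropout pixel count", {
  im <- fx_pool()[[1]]
  ident <- augmentation_config(hue_jitter = 0, sat_jitter = 0, val_jitter = 0,
                               dropout_count = c(0, 0), flip_prob = 0)
  out <- augment(im, ident, seed = 1)
  expect_identical(out$image, im$image)
  expect_equal(out$boxes, im$boxes)

  # flip mirrors box x: x' = W - x - w
  w_img <- dim(im$image)[2]
  flip <- augmentation_config(hue_jitter = 0, sat_jitter = 0, val_jitter = 0,
                              dropout_count = c(0, 0), flip_prob = 1)
  out <- augment(im, flip, seed = 2)
  expect_equal(out$boxes$x, w_img - im$boxes$x - im$boxes$w)
  expect_identical(bhvtrack:::labeled_pixels(out),
                   bhvtrack:::labeled_pixels(im)[, w_img:1, , drop = FALSE])

  # one fixed-size dropout patch alters exactly side^2 pixels
  drop1 <- augmentation_config(hue_jitter = 0, sat_jitter = 0, val_jitter = 0,
                               dropout_count = c(1, 1),
                               dropout_frac = c(0.1, 0.1), flip_prob = 0)
  side <- round(0.1 * min(dim(im$image)[1:2]))
  out <- augment(im, drop1, seed = 3)
  diffpx <- apply(bhvtrack:::labeled_pixels(out) != bhvtrack:::labeled_pixels(im),
                  c(1, 2), any)
  expect_equal(sum(diffpx), side^2)
})

test_that("augmentation keeps every box inside its image (property)", {
  cfg <- augmentation_config(seed = NULL)
  for (s in 1:20) {
    im <- fx_pool()[[1 + s %% 3]]
    out <- augment(im, cfg, seed = s)
    d <- dim(out$image)
    expect_true(all(out$boxes$x >= 0 & out$boxes$y >= 0 &
                    out$boxes$x + out$boxes$w <= d[2] &
                    out$boxes$y + out$boxes$h <= d[1]))
  }
})

test_that("resize_with_boxes scales boxes per axis and preserves centers", {
  im <- labeled_image(array(0.5, dim = c(100, 100, 3)),
                      data.frame(x = 10, y = 10, w = 30, h = 30, class = "m"))
  expect_identical(resize_with_boxes(im, c(100, 100)), im)
  out <- resize_with_boxes(im, c(200, 200))
  expect_equal(unname(unlist(out$boxes[1, 1:4])), c(20, 20, 60, 60))
  # non-uniform scaling against an independent per-axis oracle
  im2 <- fx_pool()[[2]]
  tgt <- c(90, 90)
  out2 <- resize_with_boxes(im2, tgt)
  d <- dim(im2$image)
  sx <- tgt[2] / d[2]; sy <- tgt[1] / d[1]
  for (i in seq_len(nrow(im2$boxes))) {
    expect_equal(out2$boxes$x[i], round(im2$boxes$x[i] * sx))
    expect_equal(out2$boxes$y[i], round(im2$boxes$y[i] * sy))
    expect_equal(out2$boxes$x[i] + out2$boxes$w[i],
                 round((im2$boxes$x[i] + im2$boxes$w[i]) * sx))
    expect_equal(out2$boxes$y[i] + out2$boxes$h[i],
                 round((im2$boxes$y[i] + im2$boxes$h[i]) * sy))
    # relative center within a pixel
    cx_rel_in <- (im2$boxes$x[i] + im2$boxes$w[i] / 2) / d[2]
    cx_rel_out <- (out2$boxes$x[i] + out2$boxes$w[i] / 2) / tgt[2]
    expect_lt(abs(cx_rel_in - cx_rel_out) * tgt[2], 1)
  }
})

test_that("CSV annotations round-trip; malformed rows name the line", {
  ann <- data.frame(video = c("a", "a", "b"), frame = c(0L, 4L, 2L),
                    x = c(1, 5.5, 9), y = c(2, 6, 10), w = c(3, 7, 11),
                    h = c(4, 8, 12), class = c("m", "m", "marker_red"))
  path <- file.path(withr::local_tempdir(), "ann.csv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back, ann)
  bad <- ann; bad$w[2] <- -3
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_annotations(path), "line 3")
  extra <- ann; extra$note <- "x"
  expect_warning(write_annotations(extra, path), "note")
})

test_that("COCO-dialect annotations parse and round-trip", {
  dir <- withr::local_tempdir()
  # hand-written 3-record fixture
  coco <- file.path(dir, "hand.json")
  writeLines('{
    "images": [
      {"id": 1, "file_name": "v1_000000.png", "video": "v1", "frame": 0},
      {"id": 2, "file_name": "v1_000003.png", "video": "v1", "frame": 3}
    ],
    "annotations": [
      {"id": 1, "image_id": 1, "bbox": [10, 20, 30, 40], "category_id": 1},
      {"id": 2, "image_id": 1, "bbox": [50, 60, 7, 8], "category_id": 2},
      {"id": 3, "image_id": 2, "bbox": [1, 2, 3, 4], "category_id": 1}
    ],
    "categories": [
      {"id": 1, "name": "black_mouse"}, {"id": 2, "name": "marker_red"}
    ]
  }', coco)
  got <- read_annotations(coco)
  expect_equal(nrow(got), 3)
  expect_equal(got$x, c(10, 50, 1))
  expect_equal(got$h, c(40, 8, 4))
  expect_equal(got$class, c("black_mouse", "marker_red", "black_mouse"))
  # round trip through the writer
  out <- file.path(dir, "rt.json")
  write_annotations(got, out, format = "coco")
  back <- read_annotations(out)
  expect_equal(back[order(back$x), c("x", "y", "w", "h", "class")],
               got[order(got$x), c("x", "y", "w", "h", "class")],
               ignore_attr = TRUE)
})
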