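# Detector backends, letterbox geometry, training mechanics, AP evaluation.

test_that("letterbox mapping round-trips and matches the closed-form inverse", {
  set.seed(11)
  for (dims in list(c(360, 640), c(180, 320), c(100, 100), c(97, 211))) {
    frame <- array(0.5, dim = c(dims, 3))
    lb <- bhvtrack:::letterbox_frame(frame, 224)
    # independent closed form
    scale <- min(224 / dims[1], 224 / dims[2])
    expect_equal(lb$scale, scale)
    for (i in 1:5) {
      box <- bbox(runif(1, 0, dims[2] - 30), runif(1, 0, dims[1] - 30),
                  runif(1, 5, 30), runif(1, 5, 30))
      fwd <- bhvtrack:::letterbox_box(box, lb)
      back <- bhvtrack:::unletterbox_box(fwd, lb)
      expect_equal(unname(back), unname(box), tolerance = 1e-9)
      # corners recover to < 0.5 px through the network-space mapping
      expect_lt(max(abs(back - box)), 0.5)
    }
  }
})

test_that("oracle backend: exact replay, full miss, bounded jitter", {
  vid <- fx_clean()
  exact <- make_oracle_detector(vid$truth, jitter = 0, miss_rate = 0, seed = 5)
  for (i in c(1, 20, 60)) {
    dets <- detect(exact, get_frame(vid$seq, i))
    tr <- vid$truth[vid$truth$frame == i - 1L, ]
    expect_equal(nrow(dets), 1)
    expect_equal(c(dets$x, dets$y, dets$w, dets$h),
                 c(tr$box_x, tr$box_y, tr$box_w, tr$box_h))
    expect_gte(dets$p, 0.5)
  }
  blind <- make_oracle_detector(vid$truth, miss_rate = 1, seed = 5)
  expect_equal(nrow(detect(blind, get_frame(vid$seq, 1))), 0)
  jit <- make_oracle_detector(vid$truth, jitter = 3, seed = 6)
  worst <- 0
  for (i in seq_len(n_frames(vid$seq))) {
    dets <- detect(jit, get_frame(vid$seq, i), threshold = 0)
    tr <- vid$truth[vid$truth$frame == i - 1L, ]
    worst <- max(worst,
                 abs(dets$x - tr$box_x), abs(dets$y - tr$box_y),
                 abs(dets$x + dets$w - tr$box_x - tr$box_w),
                 abs(dets$y + dets$h - tr$box_y - tr$box_h))
  }
  expect_lte(worst, 3)
  # deterministic per (frame, seed)
  jit2 <- make_oracle_detector(vid$truth, jitter = 3, seed = 6)
  expect_equal(detect(jit, get_frame(vid$seq, 10), threshold = 0),
               detect(jit2, get_frame(vid$seq, 10), threshold = 0))
})

test_that("average precision matches a hand-tabulated precision/recall curve", {
  blank <- array(0.5, dim = c(64, 64, 3))
  gt_box <- data.frame(x = 10, y = 10, w = 20, h = 12, class = "m")
  test_set <- lapply(0:2, function(f)
    labeled_image(blank, gt_box, source = list(video = "v", frame = f)))
  far <- c(x = 40, y = 40, w = 12, h = 12)
  dets <- rbind(
    data.frame(frame = 0, x = 10, y = 10, w = 20, h = 12, label = "m", p = 0.9),
    data.frame(frame = 0, x = far[1], y = far[2], w = far[3], h = far[4],
               label = "m", p = 0.8),
    data.frame(frame = 1, x = 11, y = 10, w = 20, h = 12, label = "m", p = 0.7),
    data.frame(frame = 2, x = far[1], y = far[2], w = far[3], h = far[4],
               label = "m", p = 0.6))
  d <- make_replay_detector(dets)
  ev <- evaluate_detector(d, test_set)
  # ranked: TP .9, FP .8, TP .7, FP .6 over 3 truths
  # precision (1, 1/2, 2/3, 1/2), recall (1/3, 1/3, 2/3, 2/3)
  # envelope integral: 1/3 * 1 + 1/3 * 2/3 = 5/9
  expect_equal(ev$ap, 5 / 9)
  # perfect detector -> AP 1; silent detector -> AP 0
  perfect <- make_replay_detector(data.frame(frame = 0:2, x = 10, y = 10,
                                             w = 20, h = 12, label = "m", p = 1))
  expect_equal(evaluate_detector(perfect, test_set)$ap, 1)
  silent <- make_replay_detector(dets[0, ])
  expect_equal(evaluate_detector(silent, test_set)$ap, 0)
})

test_that("non-maximum suppression keeps the best of overlapping boxes", {
  dets <- data.frame(x = c(10, 12, 50), y = c(10, 11, 50),
                     w = c(20, 20, 10), h = c(15, 15, 10),
                     label = "m", p = c(0.9, 0.7, 0.6))
  kept <- bhvtrack:::nms_detections(dets, 0.5)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$p, c(0.9, 0.6))
})

test_that("training consumes whole batches and is deterministic under a seed", {
  pool <- fx_pool()
  sp <- list(train = pool[1:24], validation = pool[25:30], test = pool[31:36])
  class(sp) <- "bhv_split"
  cfg <- training_config(input_size = 96, epochs = 2, seed = 3)
  d1 <- suppressMessages(train_detector(sp, cfg, verbose = FALSE))
  # 2 epochs x ceil(24/16) = 4 optimizer steps; batch sizes 16, 8 per epoch
  expect_equal(nrow(d1$history$steps), 4)
  expect_equal(d1$history$steps$n_images, c(16, 8, 16, 8))
  d2 <- suppressMessages(train_detector(sp, cfg, verbose = FALSE))
  expect_identical(d1$history$epochs$val_loss, d2$history$epochs$val_loss)
  expect_identical(d1$weights[[6]]$W, d2$weights[[6]]$W)
  # detections: p in [0, 1], sorted descending; threshold 1 boundary
  f <- bhvtrack:::labeled_pixels(pool[[40]])
  dets <- detect(d1, f, threshold = 0.001)
  if (nrow(dets) > 0) {
    expect_true(all(dets$p >= 0.001 & dets$p <= 1))
    expect_true(all(diff(dets$p) <= 0))
  }
  expect_true(all(detect(d1, f, threshold = 1)$p == 1))
})

test_that("training loss decreases over epochs on a synthetic set", {
  pool <- fx_pool()
  sp <- split_dataset(pool, c(0.8, 0.1, 0.1), seed = 5)
  cfg <- training_config(input_size = 96, epochs = 6, seed = 4)
  d <- suppressMessages(train_detector(sp, cfg, verbose = FALSE))
  ep <- d$history$epochs$train_loss
  expect_lt(ep[length(ep)], ep[1])
  expect_true(all(is.finite(ep)))
})

test_that("training rejects empty or unlabeled training sets", {
  pool <- fx_pool()
  empty <- list(train = list(), validation = list(), test = list())
  class(empty) <- "bhv_split"
  expect_error(train_detector(empty, training_config(input_size = 96)),
               "empty training set")
  nolab <- pool[[1]]
  nolab$boxes <- nolab$boxes[0, ]
  sp <- list(train = list(nolab), validation = list(), test = list())
  class(sp) <- "bhv_split"
  expect_error(train_detector(sp, training_config(input_size = 96)),
               ">= 1 box")
})

test_that("blob backend boxes the largest foreground component", {
  vid <- fx_clean()
  bg <- fx_clean_bg()
  d <- make_blob_detector(bg)
  f <- get_frame(vid$seq, 30)
  dets <- detect(d, f, threshold = 0.1)
  expect_equal(nrow(dets), 1)
  tr <- vid$truth[vid$truth$frame == 29L, ]
  expect_gt(bbox_iou(c(x = dets$x, y = dets$y, w = dets$w, h = dets$h),
                     c(x = tr$box_x, y = tr$box_y, w = tr$box_w, h = tr$box_h)),
            0.5)
})
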