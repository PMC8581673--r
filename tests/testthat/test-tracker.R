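# Per-frame pipeline, whole-video tracking, correction, feedback loop.

test_that("select_detection: highest p wins; ties break by area then order", {
  expect_null(select_detection(NULL))
  expect_null(select_detection(data.frame(x = numeric(0), y = numeric(0),
                                          w = numeric(0), h = numeric(0),
                                          label = character(0), p = numeric(0))))
  dets <- data.frame(x = c(0, 10, 20), y = 0, w = 10, h = 10,
                     label = "m", p = c(0.4, 0.9, 0.7))
  expect_equal(select_detection(dets)$p, 0.9)
  expect_equal(select_detection(dets)$x, 10)
  tie <- data.frame(x = c(0, 30), y = 0, w = c(10, 20), h = c(10, 20),
                    label = "m", p = 0.8)
  for (perm in list(1:2, 2:1)) {
    pick <- select_detection(tie[perm, ])
    expect_equal(pick$w, 20)  # larger area wins under either ordering
  }
  same <- data.frame(x = c(5, 25), y = 0, w = 10, h = 10, label = "m", p = 0.8)
  expect_equal(select_detection(same)$x, 5)  # then first in list
})

test_that("enlarge_box scales sides about the center and clamps at frame edges", {
  expect_equal(unname(enlarge_box(bbox(40, 40, 20, 20), 1.5, c(360, 640))),
               c(35, 35, 30, 30))
  expect_equal(unname(enlarge_box(bbox(7, 9, 12, 14), 1, c(360, 640))),
               c(7, 9, 12, 14))
  # exhaustive corner placements on a 20x20 toy frame
  for (x in 0:14) for (y in 0:14) {
    out <- enlarge_box(bbox(x, y, 6, 6), 1.5, c(20, 20))
    expect_gte(out[["x"]], 0); expect_gte(out[["y"]], 0)
    expect_lte(out[["x"]] + out[["w"]], 20)
    expect_lte(out[["y"]] + out[["h"]], 20)
    # rounding outward can add at most one pixel per side before clamping
    expect_lte(out[["w"]] * out[["h"]], (6 * 1.5 + 2)^2)
    # coverage never shrinks when the enlarged box stays in frame
    if (x >= 2 && y >= 2 && x <= 12 && y <= 12) {
      expect_lte(out[["x"]], x); expect_lte(out[["y"]], y)
      expect_gte(out[["x"]] + out[["w"]], x + 6)
      expect_gte(out[["y"]] + out[["h"]], y + 6)
    }
  }
})

test_that("track_frame statuses: tracked, undetected, fallback to box center", {
  vid <- fx_clean()
  bg <- fx_clean_bg()
  det <- make_oracle_detector(vid$truth, seed = 2)
  pt <- track_frame(get_frame(vid$seq, 10), det, bg)
  expect_equal(pt$status, "tracked")
  tr <- vid$truth[vid$truth$frame == 9L, ]
  expect_lt(sqrt((pt$x - tr$x)^2 + (pt$y - tr$y)^2), 0.5)

  blind <- make_oracle_detector(vid$truth, miss_rate = 1, seed = 2)
  pt2 <- track_frame(get_frame(vid$seq, 10), blind, bg)
  expect_equal(pt2$status, "undetected")
  expect_true(is.na(pt2$x))

  # detection present but target invisible to subtraction -> box-center fallback
  flat <- bg$reference
  pt3 <- track_frame(flat, det, bg, frame_index = 9L)
  expect_equal(pt3$status, "fallback_box_center")
  expect_equal(pt3$x, pt3$box_x + (pt3$box_w - 1) / 2)
})

test_that("track_video: one point per frame, drop log agreement, determinism", {
  vid <- fx_clean()
  bg <- fx_clean_bg()
  det <- make_oracle_detector(vid$truth, seed = 4)
  traj <- track_video(vid$seq, det, bg, verbose = FALSE)
  expect_equal(nrow(traj$points), n_frames(vid$seq))
  expect_equal(traj$points$frame, 0:(n_frames(vid$seq) - 1))
  expect_true(all(traj$points$status == "tracked"))

  lossy <- make_oracle_detector(vid$truth, miss_rate = 0.2, seed = 8)
  t2 <- track_video(vid$seq, lossy, bg, verbose = FALSE)
  expect_equal(sum(t2$points$status == "undetected"), length(lossy$log$missed))
  expect_equal(t2$points$frame[t2$points$status == "undetected"],
               sort(lossy$log$missed))

  lossy3 <- make_oracle_detector(vid$truth, miss_rate = 0.2, seed = 8)
  t3 <- track_video(vid$seq, lossy3, bg, verbose = FALSE)
  expect_identical(t2$points, t3$points)
})

test_that("manual corrections are targeted, immutable, and batch-order independent", {
  vid <- fx_clean()
  bg <- fx_clean_bg()
  det <- make_oracle_detector(vid$truth, miss_rate = 0.3, seed = 12)
  traj <- track_video(vid$seq, det, bg, verbose = FALSE)
  expect_identical(manual_correct(traj, data.frame(frame = integer(0),
                                                   x = numeric(0),
                                                   y = numeric(0)))$points,
                   traj$points)
  miss <- traj$points$frame[traj$points$status == "undetected"]
  expect_gt(length(miss), 1)
  fix <- data.frame(frame = miss, x = seq_along(miss), y = 2 * seq_along(miss))
  one <- manual_correct(traj, fix)
  expect_true(all(one$points$status[one$points$frame %in% miss] == "manual"))
  expect_equal(one$points$x[one$points$frame %in% miss], fix$x)
  # original untouched
  expect_true(all(traj$points$status[traj$points$frame %in% miss] == "undetected"))
  # two batches == one batch
  half <- ceiling(length(miss) / 2)
  two <- manual_correct(manual_correct(traj, fix[1:half, ]),
                        fix[(half + 1):nrow(fix), ])
  expect_identical(two$points, one$points)
  expect_error(manual_correct(traj, data.frame(frame = 10000, x = 1, y = 1)),
               "out of range")
})

test_that("collect_failures flags undetected, low-confidence, and jump frames", {
  vid <- fx_clean()
  bg <- fx_clean_bg()
  det <- make_oracle_detector(vid$truth, seed = 2)
  smooth <- track_video(vid$seq, det, bg, verbose = FALSE)
  none <- collect_failures(smooth, vid$seq, criteria = list(jump_px = Inf))
  expect_length(none$indices, 0)

  lossy <- make_oracle_detector(vid$truth, miss_rate = 0.1, seed = 3)
  t2 <- track_video(vid$seq, lossy, bg, verbose = FALSE)
  fails <- collect_failures(t2, vid$seq, criteria = list(jump_px = Inf))
  expect_setequal(fails$indices, t2$points$frame[t2$points$status == "undetected"])
  expect_length(fails$frames, length(fails$indices))

  # a single 80-px jump at a known frame, against a hand-built trajectory
  jumpy <- smooth
  jumpy$points$x[30] <- jumpy$points$x[30] + 80
  got <- collect_failures(jumpy, vid$seq, criteria = list(jump_px = 40))
  expect_true(jumpy$points$frame[30] %in% got$indices)
  expect_true(all(got$reasons$reason[got$reasons$frame == jumpy$points$frame[30]]
                  == "incorrect"))
  # export for relabeling produces images + a parseable annotation template
  dir <- file.path(withr::local_tempdir(), "failures")
  collect_failures(jumpy, vid$seq, criteria = list(jump_px = 40), out_dir = dir)
  expect_true(file.exists(file.path(dir, "annotations_template.csv")))
  tmpl <- read_annotations(file.path(dir, "annotations_template.csv"))
  expect_true(nrow(tmpl) >= 1)
})

test_that("short undetected gaps can be bridged linearly on request", {
  vid <- fx_clean()
  bg <- fx_clean_bg()
  det <- make_oracle_detector(vid$truth, seed = 2)
  traj <- track_video(vid$seq, det, bg, verbose = FALSE)
  g <- traj
  g$points$x[11:12] <- NA; g$points$y[11:12] <- NA
  g$points$status[11:12] <- "undetected"
  filled <- interpolate_gaps(g, max_gap = 5)
  expect_false(any(is.na(filled$points$x[11:12])))
  expect_equal(filled$points$x[11],
               g$points$x[10] + (g$points$x[13] - g$points$x[10]) / 3)
  long <- traj
  long$points$x[20:28] <- NA; long$points$status[20:28] <- "undetected"
  still <- interpolate_gaps(long, max_gap = 5)
  expect_true(all(is.na(still$points$x[20:28])))
})

test_that("trajectories round-trip through CSV + sidecar", {
  vid <- fx_clean()
  bg <- fx_clean_bg()
  det <- make_oracle_detector(vid$truth, seed = 2)
  traj <- track_video(vid$seq, det, bg, verbose = FALSE)
  path <- file.path(withr::local_tempdir(), "traj.csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$points$x, traj$points$x)
  expect_equal(back$fps, traj$fps)
  expect_equal(back$working_size, unname(traj$working_size))
})
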