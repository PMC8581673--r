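# Kinematics, occupancy maps, region dwell, ground-truth error, color identity.

make_traj <- function(x, y, fps = 30, status = NULL, px_per_cm = NA_real_,
                      working_size = c(180, 320)) {
  n <- length(x)
  structure(list(points = data.frame(
    frame = 0:(n - 1), x = x, y = y,
    status = status %||% ifelse(is.na(x), "undetected", "tracked"),
    p = 1, box_x = NA_real_, box_y = NA_real_, box_w = NA_real_,
    box_h = NA_real_), fps = fps, px_per_cm = px_per_cm,
    working_size = working_size, provenance = list()),
    class = "bhv_trajectory")
}

test_that("kinematics: stationary, constant-speed, and direct-sum oracle", {
  still <- make_traj(rep(5, 10), rep(7, 10))
  k <- kinematics(still)
  expect_equal(k$totals$total_distance, 0)
  expect_equal(k$totals$mean_speed, 0)

  walk <- make_traj(seq(0, 27, by = 3), rep(10, 10))
  k2 <- kinematics(walk)
  expect_true(all(k2$steps$speed == 90))
  expect_equal(k2$totals$distance_unit, "px")

  set.seed(40)
  x <- cumsum(rnorm(50)); y <- cumsum(rnorm(50))
  k3 <- kinematics(make_traj(x, y))
  expect_equal(k3$totals$total_distance,
               sum(sqrt(diff(x)^2 + diff(y)^2)), tolerance = 1e-9)
  # calibration converts to cm
  kcal <- kinematics(make_traj(x, y, px_per_cm = 4))
  expect_equal(kcal$totals$total_distance, k3$totals$total_distance / 4)
  expect_equal(kcal$totals$speed_unit, "cm/s")
})

test_that("kinematics excludes steps across gaps and speeds are translation invariant", {
  x <- c(0, 3, NA, 100, 103); y <- c(0, 0, NA, 0, 0)
  k <- kinematics(make_traj(x, y))
  expect_equal(k$totals$n_steps, 2)      # 0->1 and 3->4 only
  expect_equal(k$totals$total_distance, 6)
  set.seed(41)
  xx <- cumsum(rnorm(30)) + 50; yy <- cumsum(rnorm(30)) + 50
  a <- kinematics(make_traj(xx, yy))
  b <- kinematics(make_traj(xx + 17.3, yy - 8.1))
  expect_equal(a$steps$speed, b$steps$speed, tolerance = 1e-12)
  expect_error(kinematics(make_traj(c(NA, NA, 1), c(NA, NA, 1))), "no valid steps")
})

test_that("time heat map conserves tracked time; speed map leaves unvisited bins NA", {
  onebin <- make_traj(rep(5, 300), rep(5, 300))
  hm <- occupancy_heatmap(onebin, "time", bin_px = 16)
  expect_equal(hm$grid[1, 1], 10)
  expect_equal(sum(hm$grid), 10)

  set.seed(42)
  x <- runif(200, 0, 319); y <- runif(200, 0, 179)
  x[sample(200, 30)] <- NA; y[is.na(x)] <- NA
  rnd <- make_traj(x, y)
  hm2 <- occupancy_heatmap(rnd, "time", bin_px = 16)
  expect_equal(sum(hm2$grid), sum(!is.na(x)) / 30, tolerance = 1e-9)

  sp <- occupancy_heatmap(make_traj(c(5, 8, NA, 100), c(5, 5, NA, 100)), "speed",
                          bin_px = 16)
  expect_equal(sp$grid[1, 1], 90)        # one visited bin: 3 px * 30 fps
  expect_true(is.na(sp$grid[5, 5]))      # never visited -> absent, not zero
})

test_that("heat-map bins match a hand tabulation on a 2x2 toy grid", {
  # extent 32x32 at bin 16 -> 2x2 bins; place frames by hand
  x <- c(2, 3, 20, 21, 22, 2); y <- c(2, 2, 2, 20, 20, 20)
  hm <- occupancy_heatmap(make_traj(x, y, fps = 1, working_size = c(32, 32)),
                          "time", bin_px = 16)
  expect_equal(hm$grid, matrix(c(2, 1, 1, 2), 2, 2), ignore_attr = TRUE)
})

test_that("region dwell accumulates time and counts boundary crossings", {
  vid <- fx_clean()
  bg <- fx_clean_bg()
  det <- make_oracle_detector(vid$truth, seed = 2)
  traj <- track_video(vid$seq, det, bg, verbose = FALSE)
  all_region <- list(everything = c(0, 0, 320, 180))
  dw <- region_dwell(traj, all_region)
  expect_equal(dw$time_s, nrow(traj$points) / traj$fps)
  expect_equal(dw$visits, 1)

  # hand-built fixture entering the right half three times
  x <- c(10, 60, 20, 70, 30, 80, 90, 10, 5, 2)
  tr <- make_traj(x, rep(10, 10), fps = 10)
  dw2 <- region_dwell(tr, list(right = c(50, 0, 270, 180),
                               left = c(0, 0, 49.5, 180)))
  expect_equal(dw2$visits[dw2$region == "right"], 3)
  expect_equal(dw2$time_s[dw2$region == "right"], 4 / 10)
  # disjoint partition: dwell sums to <= total duration
  expect_lte(sum(dw2$time_s), 1)
})

test_that("error to ground truth: zero case, 3-4-5 offset, symmetry, coverage", {
  vid <- fx_clean()
  tt <- vid$truth
  self <- error_to_ground_truth(tt, tt)
  expect_equal(self$mean, 0)
  expect_equal(self$coverage, 1)
  off <- tt; off$x <- off$x + 3; off$y <- off$y + 4
  e <- error_to_ground_truth(tt, off)
  expect_true(all(abs(e$per_frame$distance - 5) < 1e-12))
  # symmetry
  bg <- fx_clean_bg()
  det <- make_oracle_detector(tt, jitter = 4, seed = 5)
  traj <- track_video(vid$seq, det, bg, verbose = FALSE)
  ab <- error_to_ground_truth(traj, tt)
  ba <- error_to_ground_truth(tt, traj)
  expect_equal(ab$mean, ba$mean)
  expect_equal(ab$per_frame$distance, ba$per_frame$distance)
  # disjoint ranges
  late <- tt; late$frame <- late$frame + 10000
  expect_error(error_to_ground_truth(tt, late), "do not overlap")
})

test_that("color identity: pure marker, unknown, greedy exclusive assignment", {
  frame <- array(0, dim = c(60, 100, 3))
  frame[11:20, 11:20, 3] <- 1                      # blue patch in box 1
  frame[11:20, 61:70, 2] <- 0.9                    # green patch in box 2
  frame[13:14, 63:64, 3] <- 1                      # a few blue px in box 2
  dets <- data.frame(x = c(8, 58), y = c(8, 8), w = 16, h = 16,
                     label = "m", p = c(0.9, 0.8))
  ids <- color_identity(frame, dets)
  expect_equal(ids, c("blue", "green"))
  # box with no marker pixels -> unknown
  empty_det <- data.frame(x = 35, y = 35, w = 10, h = 10, label = "m", p = 0.5)
  expect_equal(color_identity(frame, empty_det), "unknown")
  # overlapping hue ranges are rejected
  bad <- list(a = list(h = c(0.2, 0.5), s_min = 0.3, v_min = 0.2),
              b = list(h = c(0.4, 0.7), s_min = 0.3, v_min = 0.2))
  expect_error(color_identity(frame, dets, markers = bad), "overlap")
})

test_that("two-animal tracking with distinct markers yields zero identity swaps", {
  vid <- fixture("two_animal", function()
    generate_arena_video(scene_config("two_animal", n_frames = 50,
                                      size = c(180, 320), seed = 77)))
  swaps <- 0
  for (i in seq_len(n_frames(vid$seq))) {
    f <- get_frame(vid$seq, i)
    tr <- vid$truth[vid$truth$frame == i - 1L, ]
    dets <- data.frame(x = tr$box_x, y = tr$box_y, w = tr$box_w, h = tr$box_h,
                       label = "m", p = 1)
    ids <- color_identity(f, dets)
    if (!identical(ids[order(tr$target)], c("blue", "green"))) swaps <- swaps + 1
  }
  expect_equal(swaps, 0)
})
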