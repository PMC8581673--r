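# Shared fixtures, generated once per test run and memoised. All fixtures
# are built in code from the synthetic scene generator; no data files.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fix[[name]])) .fix[[name]] <- make()
  .fix[[name]]
}

# small clean-regime video + ground truth (fast; used across modules)
fx_clean <- function() fixture("clean", function()
  generate_arena_video(scene_config("clean", n_frames = 60,
                                    size = c(180, 320), seed = 101)))

# exact empty-arena reference for the clean fixture (the preferred
# background source when one exists; sub-pixel assertions rely on it)
fx_clean_bg <- function() fixture("clean_bg", function() {
  cfg <- scene_config("clean", n_frames = 60, size = c(180, 320), seed = 101)
  estimate_background(NULL, method = "supplied",
                      reference = bhvtrack:::render_background(cfg)$bg)
})

# noise-free single frame + its exact background, for sub-pixel checks
fx_flat <- function() fixture("flat", function() {
  cfg <- scene_config("clean", n_frames = 3, size = c(120, 160), seed = 7,
                      noise_sd = 0)
  list(vid = generate_arena_video(cfg), cfg = cfg)
})

# small labeled-image pool with three target sizes (training fixtures)
fx_pool <- function() fixture("pool", function() {
  mk <- function(seed, a, b, col) scene_config(
    "clean", n_frames = 16, size = c(120, 160), seed = seed,
    targets = list(list(axes = c(a = a, b = b), color = rep(col, 3),
                        marker = NULL, bounds = NULL)))
  c(generate_labeled_dataset(mk(11, 9, 7, 0.12), 16),
    generate_labeled_dataset(mk(12, 11, 8, 0.10), 16),
    generate_labeled_dataset(mk(13, 8, 6, 0.15), 16))
})

# brute-force even-odd point-in-polygon (boundary excluded); the package
# rasterizer is checked against this on polygons with irrational-ish
# vertices so lattice points never sit on an edge
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > py) != (poly[j, 2] > py) &&
        px < (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) /
             (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

# brute-force 8-connected labeling via repeated flood fill
label8_oracle <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (x in seq_len(ncol(mask))) for (y in seq_len(nrow(mask))) {
    if (!mask[y, x] || lab[y, x] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(y, x))
    lab[y, x] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        ny <- p[1] + dy; nx <- p[2] + dx
        if (ny >= 1 && ny <= nrow(mask) && nx >= 1 && nx <= ncol(mask) &&
            mask[ny, nx] && lab[ny, nx] == 0L) {
          lab[ny, nx] <- nxt
          queue[[length(queue) + 1]] <- c(ny, nx)
        }
      }
    }
  }
  lab
}
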