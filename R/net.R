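# Internals of the trainable detector: a compact fully-convolutional network
# with a single-scale grid head, trained by backpropagation.
#
# Feature maps are (channels, h*w*n) matrices with spatial index s = y + h*x
# per image block; convolutions are im2col (C++) followed by BLAS matrix
# products, which keeps a desk-scale training run fast without any deep
# learning framework. Architecture: five 3x3 convolutions (strides
# 2,2,2,2,1; channels 3 -> 8 -> 16 -> 32 -> 32 -> 128, leaky-ReLU 0.1) and a
# 1x1 head predicting, per grid cell and anchor, (tx, ty, tw, th,
# objectness, class scores). The grid stride is 16 px — fine enough that
# within-cell offset regression resolves an animal-sized box — so input S
# gives an S/16 x S/16 grid.

NET_CHANNELS <- c(3, 8, 16, 32, 32, 128)
NET_LAYER_STRIDES <- c(2L, 2L, 2L, 2L, 1L)
NET_STRIDE <- 16L
LEAKY_SLOPE <- 0.1
# Output gain on the box-regression channels: raw activations are scaled by
# this factor before being read as cell offsets / sqrt-sizes, the usual
# "box-target standard deviation" normalization of detection heads. It keeps
# the effective curvature of the squared-error coordinate terms two orders
# of magnitude below the objectness terms, so one learning rate serves both.
COORD_GAIN <- 0.1

net_init <- function(input_size, n_classes, anchors, seed) {
  n_anchors <- nrow(anchors)
  with_seed(seed, {
    layers <- list()
    for (l in seq_len(length(NET_CHANNELS) - 1)) {
      ic <- NET_CHANNELS[l]; oc <- NET_CHANNELS[l + 1]
      fan_in <- ic * 9
      layers[[l]] <- list(
        W = matrix(rnorm(oc * fan_in, 0, sqrt(2 / fan_in)), oc, fan_in),
        b = numeric(oc), k = 3L, stride = NET_LAYER_STRIDES[l], pad = 1L,
        activ = "leaky")
    }
    per_anchor <- 5L + n_classes
    oc_head <- n_anchors * per_anchor
    ic <- NET_CHANNELS[length(NET_CHANNELS)]
    b_head <- numeric(oc_head)
    base <- (seq_len(n_anchors) - 1) * per_anchor
    # start boxes at the cell center with the anchor's size, and objectness
    # at a low prior so early training is not swamped by the no-object term
    # (biases are stored on the raw scale, hence the 1/COORD_GAIN)
    b_head[base + 1L] <- 0.5 / COORD_GAIN
    b_head[base + 2L] <- 0.5 / COORD_GAIN
    b_head[base + 3L] <- sqrt(anchors[, 1] / input_size) / COORD_GAIN
    b_head[base + 4L] <- sqrt(anchors[, 2] / input_size) / COORD_GAIN
    b_head[base + 5L] <- -2
    # 3x3 head: offset/size regression benefits from seeing the 3x3 feature
    # neighborhood of each cell
    layers[[length(layers) + 1]] <- list(
      W = matrix(rnorm(oc_head * ic * 9, 0, 0.01), oc_head, ic * 9),
      b = b_head, k = 3L, stride = 1L, pad = 1L, activ = "linear")
    layers
  })
}

leaky <- function(z) ifelse(z > 0, z, LEAKY_SLOPE * z)
leaky_grad <- function(z) ifelse(z > 0, 1, LEAKY_SLOPE)

# Forward pass over a batch. fmat: (3, S*S*n). Returns head output and,
# optionally, the caches needed for backprop.
net_forward <- function(layers, fmat, size, n, keep_cache = FALSE) {
  h <- size; w <- size
  Fcur <- fmat
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    if (ly$k == 1L) {
      cols <- Fcur
    } else {
      cols <- cpp_im2col(Fcur, h, w, n, ly$k, ly$stride, ly$pad)
      h <- (h + 2 * ly$pad - ly$k) %/% ly$stride + 1L
      w <- (w + 2 * ly$pad - ly$k) %/% ly$stride + 1L
    }
    Z <- ly$W %*% cols + ly$b
    if (keep_cache) cache[[l]] <- list(cols = cols, Z = Z, h = h, w = w)
    Fcur <- if (ly$activ == "leaky") leaky(Z) else Z
  }
  list(out = Fcur, grid = h, cache = cache)
}

# Backward pass; returns per-layer gradients (dW, db).
net_backward <- function(layers, cache, d_out, size, n) {
  grads <- vector("list", length(layers))
  dF <- d_out
  for (l in rev(seq_along(layers))) {
    ly <- layers[[l]]
    dZ <- if (ly$activ == "leaky") dF * leaky_grad(cache[[l]]$Z) else dF
    grads[[l]] <- list(dW = tcrossprod(dZ, cache[[l]]$cols), db = rowSums(dZ))
    if (l > 1) {
      dcols <- crossprod(ly$W, dZ)
      if (ly$k == 1L) {
        dF <- dcols
      } else {
        hin <- if (l > 1) cache[[l - 1]]$h else size
        win <- hin
        dF <- cpp_col2im(dcols, nrow(cache[[l - 1]]$Z), hin, win, n,
                         ly$k, ly$stride, ly$pad)
      }
    }
  }
  grads
}

# Loss and head gradient for one batch.
#
# targets: list (one element per image) of data frames with letterboxed
# ground truth (cx, cy, w, h in input pixels; class index 1..C). Loss terms
# are summed (not averaged) over the batch, YOLO-style: squared error on
# linear within-cell center offsets and on the square root of normalized box
# sides for the responsible anchor (both linear readouts, so coordinate
# gradients do not vanish late in training), logistic objectness with
# down-weighted no-object cells, and a softmax class term when there is more
# than one class.
yolo_loss <- function(Z, n, grid, input_size, anchors, n_classes, targets, wts) {
  A <- nrow(anchors)
  per <- 5L + n_classes
  ncell <- grid * grid
  dZ <- matrix(0, nrow(Z), ncol(Z))
  obj_rows <- (seq_len(A) - 1) * per + 5L
  obj_target <- matrix(0, A, ncol(Z))
  loss_coord <- 0; loss_class <- 0
  for (img in seq_len(n)) {
    gt <- targets[[img]]
    if (is.null(gt) || nrow(gt) == 0) next
    for (g in seq_len(nrow(gt))) {
      cx <- gt$cx[g]; cy <- gt$cy[g]; bw <- gt$w[g]; bh <- gt$h[g]
      gx <- min(grid - 1L, max(0L, floor(cx / NET_STRIDE)))
      gy <- min(grid - 1L, max(0L, floor(cy / NET_STRIDE)))
      ious <- vapply(seq_len(A), function(a)
        bbox_iou(c(x = -bw / 2, y = -bh / 2, w = bw, h = bh),
                 c(x = -anchors[a, 1] / 2, y = -anchors[a, 2] / 2,
                   w = anchors[a, 1], h = anchors[a, 2])), numeric(1))
      a <- which.max(ious)
      col <- (img - 1L) * ncell + gx * grid + gy + 1L
      base <- (a - 1L) * per
      obj_target[a, col] <- 1
      g_ <- COORD_GAIN
      tx <- g_ * Z[base + 1L, col]; ty <- g_ * Z[base + 2L, col]
      tw <- g_ * Z[base + 3L, col]; th <- g_ * Z[base + 4L, col]
      xs <- cx / NET_STRIDE - gx; ys <- cy / NET_STRIDE - gy
      loss_coord <- loss_coord + wts[["coord"]] * ((tx - xs)^2 + (ty - ys)^2)
      dZ[base + 1L, col] <- dZ[base + 1L, col] + wts[["coord"]] * 2 * (tx - xs) * g_
      dZ[base + 2L, col] <- dZ[base + 2L, col] + wts[["coord"]] * 2 * (ty - ys) * g_
      us <- sqrt(bw / input_size); vs <- sqrt(bh / input_size)
      loss_coord <- loss_coord + wts[["coord"]] * ((tw - us)^2 + (th - vs)^2)
      dZ[base + 3L, col] <- dZ[base + 3L, col] + wts[["coord"]] * 2 * (tw - us) * g_
      dZ[base + 4L, col] <- dZ[base + 4L, col] + wts[["coord"]] * 2 * (th - vs) * g_
      if (n_classes > 1) {
        zc <- Z[base + 5L + seq_len(n_classes), col]
        zc <- zc - max(zc)
        p <- exp(zc) / sum(exp(zc))
        loss_class <- loss_class + wts[["class"]] * (-log(max(p[gt$class[g]], 1e-12)))
        dvec <- p; dvec[gt$class[g]] <- dvec[gt$class[g]] - 1
        dZ[base + 5L + seq_len(n_classes), col] <-
          dZ[base + 5L + seq_len(n_classes), col] + wts[["class"]] * dvec
      }
    }
  }
  zo <- Z[obj_rows, , drop = FALSE]
  so <- sigmoid(zo)
  wmat <- ifelse(obj_target > 0, wts[["obj"]], wts[["noobj"]])
  eps <- 1e-12
  loss_obj <- sum(wmat * -(obj_target * log(so + eps) +
                           (1 - obj_target) * log(1 - so + eps)))
  dZ[obj_rows, ] <- dZ[obj_rows, , drop = FALSE] + wmat * (so - obj_target)
  list(loss = loss_coord + loss_obj + loss_class, dZ = dZ)
}

# Decode head output for one image block into detections (input-space px).
net_decode <- function(Zimg, grid, input_size, anchors, labels, p_floor = 1e-3) {
  A <- nrow(anchors)
  C <- length(labels)
  per <- 5L + C
  s <- 0:(grid * grid - 1)
  gx <- s %/% grid
  gy <- s %% grid
  out <- vector("list", A)
  for (a in seq_len(A)) {
    base <- (a - 1L) * per
    p_obj <- sigmoid(Zimg[base + 5L, ])
    if (C > 1) {
      zc <- Zimg[base + 5L + seq_len(C), , drop = FALSE]
      zc <- sweep(zc, 2, apply(zc, 2, max))
      pc <- exp(zc)
      pc <- sweep(pc, 2, colSums(pc), "/")
      cls <- apply(pc, 2, which.max)
      p <- p_obj * pc[cbind(cls, seq_along(cls))]
    } else {
      cls <- rep(1L, length(p_obj))
      p <- p_obj
    }
    keep <- which(p >= p_floor)
    if (length(keep) == 0) next
    bx <- (gx[keep] + clamp(COORD_GAIN * Zimg[base + 1L, keep], -0.5, 1.5)) * NET_STRIDE
    by <- (gy[keep] + clamp(COORD_GAIN * Zimg[base + 2L, keep], -0.5, 1.5)) * NET_STRIDE
    bw <- input_size * clamp(COORD_GAIN * Zimg[base + 3L, keep], 0.005, sqrt(2))^2
    bh <- input_size * clamp(COORD_GAIN * Zimg[base + 4L, keep], 0.005, sqrt(2))^2
    out[[a]] <- data.frame(x = bx - bw / 2, y = by - bh / 2, w = bw, h = bh,
                           label = labels[cls[keep]], p = p[keep])
  }
  do.call(rbind, out) %||% empty_detections()
}

# Optimizer state shared by both update rules.
optim_init <- function(layers) {
  lapply(layers, function(ly) list(
    mW = matrix(0, nrow(ly$W), ncol(ly$W)), mb = numeric(length(ly$b)),
    vW = matrix(0, nrow(ly$W), ncol(ly$W)), vb = numeric(length(ly$b))))
}

# One optimizer step: "adam" (default; adaptive per-parameter steps make the
# short, fixed training schedule usable from random init) or "sgdm"
# (momentum SGD). Global gradient-norm clipping guards against the
# occasional exploding batch.
optim_step <- function(layers, grads, state, lr, momentum, rule, t,
                       clip = 1e3) {
  gnorm <- sqrt(sum(vapply(grads, function(g)
    sum(g$dW^2) + sum(g$db^2), numeric(1))))
  scale <- if (is.finite(clip) && gnorm > clip) clip / gnorm else 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (l in seq_along(layers)) {
    gW <- scale * grads[[l]]$dW; gb <- scale * grads[[l]]$db
    if (rule == "adam") {
      state[[l]]$mW <- b1 * state[[l]]$mW + (1 - b1) * gW
      state[[l]]$mb <- b1 * state[[l]]$mb + (1 - b1) * gb
      state[[l]]$vW <- b2 * state[[l]]$vW + (1 - b2) * gW^2
      state[[l]]$vb <- b2 * state[[l]]$vb + (1 - b2) * gb^2
      mhW <- state[[l]]$mW / (1 - b1^t); mhb <- state[[l]]$mb / (1 - b1^t)
      vhW <- state[[l]]$vW / (1 - b2^t); vhb <- state[[l]]$vb / (1 - b2^t)
      layers[[l]]$W <- layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
      layers[[l]]$b <- layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
    } else {
      state[[l]]$mW <- momentum * state[[l]]$mW - lr * gW
      state[[l]]$mb <- momentum * state[[l]]$mb - lr * gb
      layers[[l]]$W <- layers[[l]]$W + state[[l]]$mW
      layers[[l]]$b <- layers[[l]]$b + state[[l]]$mb
    }
  }
  list(layers = layers, state = state, gnorm = gnorm)
}
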