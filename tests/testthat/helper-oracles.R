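# Independent oracles used across the suite. Each is a deliberately naive
# implementation (loops, enumeration, rasterization) kept separate from the
# code paths it checks.

# internal helpers exercised directly by the oracles and unit tests
conv2d_fwd <- ripedetr:::conv2d_fwd
act_fwd <- ripedetr:::act_fwd

# dense 2D convolution by explicit loops (same padding, stride 1, no bias)
naive_conv2d <- function(x, w_mat, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  cout <- ncol(w_mat)
  pad <- (k - 1) %/% 2
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  # w_mat rows ordered as (di, dj, channel) blocks matching im2col
  out <- array(0, c(H, W, cout))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    patch <- numeric(k * k * C)
    idx <- 1
    for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
      patch[idx:(idx + C - 1)] <- xp[i + di, j + dj, ]
      idx <- idx + C
    }
    out[i, j, ] <- as.numeric(patch %*% w_mat)
  }
  out
}

# rasterized intersection/union of two xyxy boxes by pixel-center counting
# (the count factorizes per axis for axis-aligned boxes, so the grid can be
# very fine)
raster_iou <- function(a, b, cells = 20000) {
  xmin <- min(a[1], b[1]); xmax <- max(a[3], b[3])
  ymin <- min(a[2], b[2]); ymax <- max(a[4], b[4])
  dx <- (xmax - xmin) / cells; dy <- (ymax - ymin) / cells
  xs <- xmin + (seq_len(cells) - 0.5) * dx
  ys <- ymin + (seq_len(cells) - 0.5) * dy
  ax <- xs >= a[1] & xs <= a[3]; ay <- ys >= a[2] & ys <= a[4]
  bx <- xs >= b[1] & xs <= b[3]; by <- ys >= b[2] & ys <= b[4]
  cell <- dx * dy
  areaA <- sum(ax) * sum(ay) * cell
  areaB <- sum(bx) * sum(by) * cell
  inter <- sum(ax & bx) * sum(ay & by) * cell
  union <- areaA + areaB - inter
  if (union == 0) 0 else inter / union
}

# inner-IoU oracle: rasterize the ratio-scaled, center-shared boxes
raster_inner_iou <- function(a, b, ratio, cells = 20000) {
  shrink <- function(bx) {
    cx <- (bx[1] + bx[3]) / 2; cy <- (bx[2] + bx[4]) / 2
    w <- (bx[3] - bx[1]) * ratio / 2; h <- (bx[4] - bx[2]) * ratio / 2
    c(cx - w, cy - h, cx + w, cy + h)
  }
  raster_iou(shrink(a), shrink(b), cells)
}

# brute-force minimal-cost assignment over all permutations (n_cols <= 6)
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(m <= 6)
  rows <- utils::combn(n, m, simplify = FALSE)
  best <- Inf
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (r in rows) for (p in perms(r)) {
    cc <- sum(cost[cbind(p, seq_len(m))])
    if (cc < best) best <- cc
  }
  best
}

# literal deformable-attention computation: loops over heads, queries and
# sampled keys, bilinear sampling done per point
naive_dat <- function(enc, x) {
  cfg <- enc$cfg
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  tok <- matrix(x, H * W, C)
  q <- tok %*% enc$wq$w + matrix(enc$wq$b, H * W, C, byrow = TRUE)
  qmap <- array(q, c(H, W, C))
  off <- conv2d_fwd(enc$off_proj, act_fwd(conv2d_fwd(enc$off_dw, qmap), "gelu"))
  p <- reference_grid(H, W, 1L)
  cellx <- if (W > 1) 2 / (W - 1) else 2
  celly <- if (H > 1) 2 / (H - 1) else 2
  offm <- matrix(off, H * W, 2)
  pts <- cbind(p[, 1] + tanh(offm[, 1]) * cfg$offset_range * cellx,
               p[, 2] + tanh(offm[, 2]) * cfg$offset_range * celly)
  # per-point bilinear sampling (scalar loop)
  samp_one <- function(pt) {
    px <- (pt[1] + 1) / 2 * (W - 1) + 1; py <- (pt[2] + 1) / 2 * (H - 1) + 1
    px <- min(max(px, 1), W); py <- min(max(py, 1), H)
    acc <- numeric(C)
    for (rx in 1:W) for (ry in 1:H) {
      g <- max(0, 1 - abs(px - rx)) * max(0, 1 - abs(py - ry))
      if (g > 0) acc <- acc + g * x[ry, rx, ]
    }
    acc
  }
  xs <- t(apply(pts, 1, samp_one))
  kk <- xs %*% enc$wk$w + matrix(enc$wk$b, nrow(xs), C, byrow = TRUE)
  vv <- xs %*% enc$wv$w + matrix(enc$wv$b, nrow(xs), C, byrow = TRUE)
  M <- cfg$heads; dh <- C %/% M
  qpos <- reference_grid(H, W, 1L)
  out <- matrix(0, H * W, C)
  for (m in seq_len(M)) {
    idx <- (m - 1) * dh + seq_len(dh)
    for (qi in seq_len(H * W)) {
      logits <- numeric(nrow(pts))
      for (ki in seq_len(nrow(pts))) {
        bias_pt <- cbind((qpos[qi, 1] - pts[ki, 1]) / 2,
                         (qpos[qi, 2] - pts[ki, 2]) / 2)
        bias <- bilinear_sample(enc$bias_table, bias_pt)[1, m]
        logits[ki] <- sum(q[qi, idx] * kk[ki, idx]) / sqrt(dh) + bias
      }
      w <- exp(logits - max(logits)); w <- w / sum(w)
      out[qi, idx] <- colSums(vv[, idx, drop = FALSE] * w)
    }
  }
  out %*% enc$wo$w + matrix(enc$wo$b, H * W, C, byrow = TRUE)
}

# hand-enumerated PR staircase integral (101-point interpolation)
staircase_ap <- function(tp, n_gt) {
  cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
  rec <- cum_tp / n_gt; prec <- cum_tp / (cum_tp + cum_fp)
  vals <- vapply(seq(0, 1, 0.01), function(r) {
    ok <- rec >= r
    if (!any(ok)) 0 else max(prec[which(ok)[1]:length(prec)])
  }, numeric(1))
  mean(vals)
}

# independent greedy matcher (same rule, separate implementation)
greedy_tp_count <- function(dets, gts, thr) {
  ord <- order(-dets$conf)
  used <- logical(nrow(gts))
  tp <- 0
  for (i in ord) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j] || gts$cls[j] != dets$cls[i]) next
      v <- iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
               as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
      if (v >= thr && v > best) { best <- v; bj <- j }
    }
    if (bj > 0) { used[bj] <- TRUE; tp <- tp + 1 }
  }
  tp
}

rand_box <- function(scale = 10) {
  cx <- runif(1, 2, scale - 2); cy <- runif(1, 2, scale - 2)
  w <- runif(1, 0.5, 4); h <- runif(1, 0.5, 4)
  c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}
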