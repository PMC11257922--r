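# Minimal CPU tensor/layer core used by the model family.
#
# Images and feature maps are numeric arrays [H, W, C]. Token sequences are
# matrices [N, d]. Every layer is a plain list carrying its configuration and
# (optionally) its weights; builders register parameter and MAC counts in a
# profile ledger so accounting and execution cannot drift apart.
#
# Counting convention (frozen; see the profiler module): one fused
# multiply-add = 1 MAC = 2 FLOPs; convolutions and matrix products are
# counted, normalization/activation/resize/softmax/pooling are not.

# ---- profile ledger ---------------------------------------------------------

new_profile <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e
}

prof_add <- function(prof, name, kind, params, macs) {
  if (!is.null(prof)) {
    prof$rows[[length(prof$rows) + 1L]] <-
      data.frame(name = name, kind = kind, params = params, macs = macs,
                 stringsAsFactors = FALSE)
  }
  invisible(NULL)
}

prof_table <- function(prof) {
  do.call(rbind, prof$rows)
}

# ---- weight init ------------------------------------------------------------

.winit <- function(dims, fan_in) {
  # He-style uniform init; callers manage the RNG seed
  s <- sqrt(2 / max(fan_in, 1))
  array(stats::runif(prod(dims), -s, s), dims)
}

# ---- primitive tensor ops ---------------------------------------------------

pad_hw <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

im2col <- function(x, k, stride, pad) {
  x <- pad_hw(x, pad)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  Ho <- (H - k) %/% stride + 1L
  Wo <- (W - k) %/% stride + 1L
  cols <- vector("list", k * k)
  idx <- 1L
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    sl <- x[seq.int(1L + di, by = stride, length.out = Ho),
            seq.int(1L + dj, by = stride, length.out = Wo), , drop = FALSE]
    cols[[idx]] <- matrix(sl, Ho * Wo, C)
    idx <- idx + 1L
  }
  list(mat = do.call(cbind, cols), ho = Ho, wo = Wo)
}

conv_out_hw <- function(h, w, k, stride, pad) {
  c((h + 2 * pad - k) %/% stride + 1L, (w + 2 * pad - k) %/% stride + 1L)
}

# ---- conv layer -------------------------------------------------------------

conv_params <- function(cin, cout, k, groups = 1, bias = FALSE) {
  k * k * (cin %/% groups) * cout + if (bias) cout else 0
}

conv_macs <- function(cin, cout, k, groups, ho, wo) {
  k * k * (cin %/% groups) * cout * ho * wo
}

nn_conv2d <- function(cin, cout, k, stride = 1, pad = (k - 1) %/% 2,
                      groups = 1, bias = FALSE, init = FALSE) {
  stopifnot(cin %% groups == 0, cout %% groups == 0)
  ly <- list(kind = "conv2d", cin = cin, cout = cout, k = k, stride = stride,
             pad = pad, groups = groups, bias = bias)
  if (init) {
    cg <- cin %/% groups
    ly$w <- lapply(seq_len(groups), function(g)
      matrix(.winit(c(k * k * cg, cout %/% groups), k * k * cg),
             k * k * cg, cout %/% groups))
    ly$b <- if (bias) numeric(cout) else NULL
  }
  ly
}

conv2d_fwd <- function(ly, x) {
  stopifnot(dim(x)[3] == ly$cin)
  g <- ly$groups
  cg_in <- ly$cin %/% g
  cg_out <- ly$cout %/% g
  outs <- vector("list", g)
  for (gi in seq_len(g)) {
    xs <- x[, , (gi - 1L) * cg_in + seq_len(cg_in), drop = FALSE]
    ic <- im2col(xs, ly$k, ly$stride, ly$pad)
    y <- ic$mat %*% ly$w[[gi]]
    outs[[gi]] <- array(y, c(ic$ho, ic$wo, cg_out))
  }
  y <- if (g == 1L) outs[[1L]] else {
    d <- dim(outs[[1L]])
    arr <- array(0, c(d[1], d[2], ly$cout))
    for (gi in seq_len(g)) arr[, , (gi - 1L) * cg_out + seq_len(cg_out)] <- outs[[gi]]
    arr
  }
  if (ly$bias) y <- sweep(y, 3, ly$b, "+")
  y
}

# ---- partial convolution ----------------------------------------------------

#' FLOPs (as multiply-accumulates) of a partial convolution
#'
#' `h * w * k^2 * cp^2`: a dense k x k convolution over the `cp` convolved
#' channels only; the remaining channels pass through for free. The profiler
#' doubles MACs to FLOPs.
#'
#' @param h,w spatial extent of the operating feature map.
#' @param k kernel size.
#' @param cp number of convolved channels.
#' @return MAC count (numeric).
#' @export
pconv_flops <- function(h, w, k, cp) {
  h * w * k^2 * cp^2
}

#' Memory-access count of a partial convolution
#'
#' Exact value `h*w*2*cp + k^2*cp^2` and its `h*w*2*cp` approximation; at
#' cp = c/4 the approximate access is a quarter of a dense convolution's
#' `h*w*2*c`.
#'
#' @inheritParams pconv_flops
#' @return list with `exact` and `approx`.
#' @export
pconv_memory_access <- function(h, w, k, cp) {
  list(exact = h * w * 2 * cp + k^2 * cp^2, approx = h * w * 2 * cp)
}

nn_pconv <- function(c_total, cp = max(1L, round(c_total / 4)), k = 3,
                     position = c("first", "last"), init = FALSE) {
  position <- match.arg(position)
  if (cp > c_total) stop("pconv: cp must not exceed the channel count")
  ly <- list(kind = "pconv", c = c_total, cp = cp, k = k, position = position,
             stride = 1L, pad = (k - 1L) %/% 2L)
  if (init) ly$w <- matrix(.winit(c(k * k * cp, cp), k * k * cp), k * k * cp, cp)
  ly
}

#' Partial-convolution forward pass
#'
#' Convolves the first (or last) `cp` channels with a dense same-padding,
#' stride-1 kernel and copies the remaining channels through bit-identically.
#'
#' @param ly a pconv layer created by the backbone builder (contains weights).
#' @param x input array \[H, W, c\].
#' @return array of the same shape.
#' @export
pconv_fwd <- function(ly, x) {
  if (dim(x)[3] != ly$c) stop("pconv: channel mismatch")
  sel <- if (ly$position == "first") seq_len(ly$cp) else (ly$c - ly$cp + 1L):ly$c
  xs <- x[, , sel, drop = FALSE]
  ic <- im2col(xs, ly$k, 1L, ly$pad)
  y <- array(ic$mat %*% ly$w, c(dim(x)[1], dim(x)[2], ly$cp))
  out <- x                         # pass-through channels copied unchanged
  out[, , sel] <- y
  out
}

# ---- normalization / activation --------------------------------------------

nn_bn <- function(c_total, init = FALSE) {
  ly <- list(kind = "bn", c = c_total)
  if (init) { ly$gamma <- rep(1, c_total); ly$beta <- numeric(c_total) }
  ly
}

bn_fwd <- function(ly, x) {
  # inference-mode affine transform (unit running statistics)
  sweep(sweep(x, 3, ly$gamma, "*"), 3, ly$beta, "+")
}

nn_ln <- function(d, init = FALSE) {
  ly <- list(kind = "ln", d = d)
  if (init) { ly$gamma <- rep(1, d); ly$beta <- numeric(d) }
  ly
}

ln_fwd <- function(ly, x) {
  # x: [N, d]
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + 1e-5)
  sweep(xc / sd, 2, ly$gamma, "*") + matrix(ly$beta, nrow(x), ly$d, byrow = TRUE)
}

act_fwd <- function(x, act) {
  switch(act,
         relu = pmax(x, 0),
         silu = x / (1 + exp(-x)),
         gelu = x * stats::pnorm(x),
         identity = x,
         stop("unknown activation: ", act))
}

# ---- pooling / resize -------------------------------------------------------

maxpool2d <- function(x, k = 3, stride = 2, pad = 1) {
  x <- pad_hw(x, pad)
  d <- dim(x)
  Ho <- (d[1] - k) %/% stride + 1L
  Wo <- (d[2] - k) %/% stride + 1L
  out <- array(-Inf, c(Ho, Wo, d[3]))
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    sl <- x[seq.int(1L + di, by = stride, length.out = Ho),
            seq.int(1L + dj, by = stride, length.out = Wo), , drop = FALSE]
    out <- pmax(out, sl)
  }
  out
}

avgpool2d <- function(x, k = 2, stride = 2) {
  d <- dim(x)
  Ho <- (d[1] - k) %/% stride + 1L
  Wo <- (d[2] - k) %/% stride + 1L
  out <- array(0, c(Ho, Wo, d[3]))
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    out <- out + x[seq.int(1L + di, by = stride, length.out = Ho),
                   seq.int(1L + dj, by = stride, length.out = Wo), , drop = FALSE]
  }
  out / (k * k)
}

upsample_nearest <- function(x, factor = 2L) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = factor), rep(seq_len(d[2]), each = factor), ,
    drop = FALSE]
}

# ---- linear / attention -----------------------------------------------------

nn_linear <- function(din, dout, bias = TRUE, init = FALSE) {
  ly <- list(kind = "linear", din = din, dout = dout, bias = bias)
  if (init) {
    ly$w <- matrix(.winit(c(din, dout), din), din, dout)
    ly$b <- if (bias) numeric(dout) else NULL
  }
  ly
}

linear_fwd <- function(ly, x) {
  y <- x %*% ly$w
  if (ly$bias) y <- sweep(y, 2, ly$b, "+")
  y
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Flatten a feature map to a token sequence and back
#'
#' `flatten_hw` turns an \[H, W, C\] map into an \[H*W, C\] token matrix
#' (row-major over positions); `unflatten_hw` is its exact inverse.
#'
#' @param x array \[H, W, C\] (or matrix for `unflatten_hw`).
#' @param h,w spatial extent to restore.
#' @return token matrix, or restored array.
#' @export
flatten_hw <- function(x) {
  d <- dim(x)
  matrix(x, d[1] * d[2], d[3])
}

#' @rdname flatten_hw
#' @export
unflatten_hw <- function(x, h, w) {
  array(x, c(h, w, ncol(x)))
}

# 2D sinusoidal position embedding for an h x w token grid, width d
sine_pos_embed_2d <- function(h, w, d, temperature = 10000) {
  stopifnot(d %% 4 == 0)
  dq <- d %/% 4
  omega <- 1 / temperature^((seq_len(dq) - 1) / dq)
  gx <- matrix(rep(seq_len(w) - 1, each = h), h * w, 1)   # column index
  gy <- matrix(rep(seq_len(h) - 1, times = w), h * w, 1)  # row index
  outx <- gx %*% t(omega); outy <- gy %*% t(omega)
  cbind(sin(outx), cos(outx), sin(outy), cos(outy))
}

#' Exact bilinear sampling of a feature map
#'
#' Samples `z` at continuous normalized points in \[-1, 1\] (cell-center
#' convention: -1 maps to the center of the first cell, +1 to the center of
#' the last). Out-of-range points are clamped to the border. The kernel is
#' `g(a, b) = max(0, 1 - |a - b|)` over integer grid locations.
#'
#' @param z array \[H, W, C\].
#' @param points n x 2 matrix of (x, y) in normalized coordinates.
#' @return n x C matrix of sampled features.
#' @export
bilinear_sample <- function(z, points) {
  d <- dim(z); H <- d[1]; W <- d[2]; C <- d[3]
  # map [-1, 1] -> [1, W] / [1, H] (cell centers)
  px <- (points[, 1] + 1) / 2 * (W - 1) + 1
  py <- (points[, 2] + 1) / 2 * (H - 1) + 1
  px <- pmin(pmax(px, 1), W)
  py <- pmin(pmax(py, 1), H)
  x0 <- pmin(floor(px), W - 1); x1 <- x0 + 1
  y0 <- pmin(floor(py), H - 1); y1 <- y0 + 1
  if (W == 1) { x0 <- x1 <- rep(1, length(px)) }
  if (H == 1) { y0 <- y1 <- rep(1, length(py)) }
  wx1 <- px - x0; wx0 <- 1 - wx1
  wy1 <- py - y0; wy0 <- 1 - wy1
  zm <- matrix(z, H * W, C)
  at <- function(yy, xx) zm[(xx - 1) * H + yy, , drop = FALSE]
  at(y0, x0) * (wy0 * wx0) + at(y0, x1) * (wy0 * wx1) +
    at(y1, x0) * (wy1 * wx0) + at(y1, x1) * (wy1 * wx1)
}

# ---- composite builders (conv+bn+act, linear) with profile registration -----

bld_convbn <- function(prof, name, cin, cout, k, stride = 1, groups = 1,
                       act = "silu", bias = FALSE, bn = TRUE, hw, init = FALSE) {
  pad <- (k - 1L) %/% 2L
  out_hw <- conv_out_hw(hw[1], hw[2], k, stride, pad)
  prof_add(prof, name, "conv2d",
           conv_params(cin, cout, k, groups, bias),
           conv_macs(cin, cout, k, groups, out_hw[1], out_hw[2]))
  obj <- list(conv = nn_conv2d(cin, cout, k, stride, pad, groups, bias, init))
  if (bn) {
    prof_add(prof, paste0(name, ".bn"), "bn", 2 * cout, 0)
    obj$bn <- nn_bn(cout, init)
  }
  obj$act <- act
  obj$out_hw <- out_hw
  obj
}

convbn_fwd <- function(obj, x) {
  y <- conv2d_fwd(obj$conv, x)
  if (!is.null(obj$bn)) y <- bn_fwd(obj$bn, y)
  act_fwd(y, obj$act)
}

bld_pconvbn <- function(prof, name, c_total, ratio, position, hw,
                        act = "identity", init = FALSE) {
  cp <- max(1L, round(c_total * ratio))
  prof_add(prof, name, "pconv",
           3 * 3 * cp * cp,
           pconv_flops(hw[1], hw[2], 3, cp))
  prof_add(prof, paste0(name, ".bn"), "bn", 2 * c_total, 0)
  list(pconv = nn_pconv(c_total, cp, 3, position, init),
       bn = nn_bn(c_total, init), act = act, out_hw = hw)
}

pconvbn_fwd <- function(obj, x) {
  act_fwd(bn_fwd(obj$bn, pconv_fwd(obj$pconv, x)), obj$act)
}

bld_linear <- function(prof, name, din, dout, tokens, bias = TRUE, init = FALSE) {
  prof_add(prof, name, "linear", din * dout + if (bias) dout else 0,
           din * dout * tokens)
  nn_linear(din, dout, bias, init)
}

bld_ln <- function(prof, name, d, init = FALSE) {
  prof_add(prof, name, "ln", 2 * d, 0)
  nn_ln(d, init)
}
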