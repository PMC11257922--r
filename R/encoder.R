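# Intra-scale feature interaction encoder: a single transformer layer over
# the deepest backbone map S5, switchable between standard multi-head
# self-attention ("mhsa", the baseline) and deformable attention ("dat").
#
# Deformable attention: a uniform reference grid of points is shifted by
# offsets predicted from the query tokens by a small offset network
# (depthwise conv -> GELU -> 1x1 projection, tanh-bounded); keys and values
# are bilinearly sampled at the shifted points, and a learned relative-
# position bias table, interpolated at the continuous query-key displacement,
# is added to the attention logits.

#' Encoder configuration
#'
#' @param mode `"mhsa"` or `"dat"`.
#' @param d_model embedding width of the encoder layer.
#' @param heads attention head count (must divide `d_model`).
#' @param ffn_dim feed-forward hidden width.
#' @param grid_factor downsampling factor of the key/value reference grid
#'   (1 keeps full S5 resolution).
#' @param offset_kernel depthwise kernel size of the offset network.
#' @param offset_range maximum offset magnitude, in reference-grid cells.
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(mode = c("mhsa", "dat"), d_model = 256L, heads = 8L,
                           ffn_dim = 1024L, grid_factor = 1L,
                           offset_kernel = 5L, offset_range = 2) {
  mode <- match.arg(mode)
  stopifnot(d_model %% heads == 0)
  structure(list(mode = mode, d_model = as.integer(d_model),
                 heads = as.integer(heads), ffn_dim = as.integer(ffn_dim),
                 grid_factor = as.integer(grid_factor),
                 offset_kernel = as.integer(offset_kernel),
                 offset_range = offset_range),
            class = "encoder_config")
}

#' Uniform reference grid in normalized coordinates
#'
#' Cell-center convention on \[-1, 1\]: the grid of an H x W map downsampled
#' by `grid_factor` has HG = H / factor rows; point (i, j) sits at the center
#' of its cell. Content-independent by construction.
#'
#' @param H,W feature-map extent.
#' @param grid_factor integer downsample factor (H, W >= grid_factor).
#' @return (HG*WG) x 2 matrix of (x, y) in \[-1, 1\], row-major over the grid.
#' @export
reference_grid <- function(H, W, grid_factor = 1L) {
  stopifnot(H >= grid_factor, W >= grid_factor)
  HG <- H %/% grid_factor; WG <- W %/% grid_factor
  cy <- if (HG == 1) 0 else 2 * (seq_len(HG) - 1) / (HG - 1) - 1
  cx <- if (WG == 1) 0 else 2 * (seq_len(WG) - 1) / (WG - 1) - 1
  cbind(x = rep(cx, each = HG), y = rep(cy, times = WG))
}

build_aifi <- function(cfg, hw, prof = NULL, init = FALSE) {
  d <- cfg$d_model
  n_tok <- hw[1] * hw[2]
  enc <- list(cfg = cfg)
  enc$wq <- bld_linear(prof, "aifi.attn.q", d, d, n_tok, init = init)
  enc$wk <- bld_linear(prof, "aifi.attn.k", d, d, n_tok, init = init)
  enc$wv <- bld_linear(prof, "aifi.attn.v", d, d, n_tok, init = init)
  enc$wo <- bld_linear(prof, "aifi.attn.o", d, d, n_tok, init = init)
  # the two attention matrix products (q k^T and weights x v)
  prof_add(prof, "aifi.attn.matmul", "attention", 0, 2 * n_tok * n_tok * d)
  if (cfg$mode == "dat") {
    kk <- cfg$offset_kernel
    prof_add(prof, "aifi.dat.offset.dw", "conv2d",
             kk * kk * d + d, kk * kk * d * n_tok)
    prof_add(prof, "aifi.dat.offset.proj", "conv2d", d * 2 + 2, d * 2 * n_tok)
    tb <- (2L * hw[1] - 1L) * (2L * hw[2] - 1L)
    prof_add(prof, "aifi.dat.bias_table", "embedding", tb * cfg$heads, 0)
    if (init) {
      enc$off_dw <- nn_conv2d(d, d, kk, groups = d, bias = TRUE, init = TRUE)
      enc$off_proj <- nn_conv2d(d, 2, 1, bias = TRUE, init = TRUE)
      enc$bias_table <- array(stats::rnorm((2 * hw[1] - 1) * (2 * hw[2] - 1) *
                                             cfg$heads, sd = 0.02),
                              c(2 * hw[1] - 1, 2 * hw[2] - 1, cfg$heads))
    }
  }
  enc$ln1 <- bld_ln(prof, "aifi.ln1", d, init = init)
  enc$ffn1 <- bld_linear(prof, "aifi.ffn.fc1", d, cfg$ffn_dim, n_tok, init = init)
  enc$ffn2 <- bld_linear(prof, "aifi.ffn.fc2", cfg$ffn_dim, d, n_tok, init = init)
  enc$ln2 <- bld_ln(prof, "aifi.ln2", d, init = init)
  enc
}

mhsa_tokens <- function(enc, q_tok, kv_tok, bias = NULL) {
  # q_tok: [Nq, d]; kv_tok: [Nk, d]; bias: optional [Nq, Nk, M] logits
  cfg <- enc$cfg
  M <- cfg$heads; dh <- cfg$d_model %/% M
  q <- linear_fwd(enc$wq, q_tok)
  k <- linear_fwd(enc$wk, kv_tok)
  v <- linear_fwd(enc$wv, kv_tok)
  out <- matrix(0, nrow(q_tok), cfg$d_model)
  for (m in seq_len(M)) {
    idx <- (m - 1L) * dh + seq_len(dh)
    logits <- (q[, idx, drop = FALSE] %*% t(k[, idx, drop = FALSE])) / sqrt(dh)
    if (!is.null(bias)) logits <- logits + bias[, , m]
    out[, idx] <- softmax_rows(logits) %*% v[, idx, drop = FALSE]
  }
  linear_fwd(enc$wo, out)
}

dat_attention <- function(enc, x) {
  # x: [H, W, d] tokens (position embedding already added)
  cfg <- enc$cfg
  d <- dim(x); H <- d[1]; W <- d[2]
  tok <- flatten_hw(x)
  q <- linear_fwd(enc$wq, tok)
  # offsets from queries via the offset network, in the query's spatial layout
  qmap <- unflatten_hw(q, H, W)
  off <- conv2d_fwd(enc$off_proj, act_fwd(conv2d_fwd(enc$off_dw, qmap), "gelu"))
  if (any(!is.finite(off))) stop("deformable attention: non-finite offsets")
  HG <- H %/% cfg$grid_factor; WG <- W %/% cfg$grid_factor
  p <- reference_grid(H, W, cfg$grid_factor)
  # offsets at grid positions (grid_factor 1: all positions), tanh-bounded to
  # offset_range cells, converted to normalized units
  offm <- matrix(off, H * W, 2)
  if (cfg$grid_factor > 1L) {
    keep_r <- round(seq(1, H, length.out = HG))
    keep_c <- round(seq(1, W, length.out = WG))
    keep <- as.vector(outer(keep_r, (keep_c - 1) * H, "+"))
    offm <- offm[keep, , drop = FALSE]
  }
  cell <- c(if (WG > 1) 2 / (WG - 1) else 2, if (HG > 1) 2 / (HG - 1) else 2)
  dp <- cbind(tanh(offm[, 1]) * cfg$offset_range * cell[1],
              tanh(offm[, 2]) * cfg$offset_range * cell[2])
  pts <- p + dp
  x_s <- bilinear_sample(x, pts)             # sampled key/value source tokens
  k <- linear_fwd(enc$wk, x_s)
  v <- linear_fwd(enc$wv, x_s)
  # relative-position bias: query positions minus sampled key positions,
  # interpolated from the learned table (displacements span [-2, 2])
  qpos <- reference_grid(H, W, 1L)
  M <- cfg$heads; dh <- cfg$d_model %/% M
  nq <- nrow(qpos); nk <- nrow(pts)
  dx <- outer(qpos[, 1], pts[, 1], "-") / 2  # -> [-1, 1]
  dy <- outer(qpos[, 2], pts[, 2], "-") / 2
  bias_pts <- cbind(as.vector(dx), as.vector(dy))
  bias <- array(bilinear_sample(enc$bias_table, bias_pts), c(nq, nk, M))
  out <- matrix(0, nq, cfg$d_model)
  for (m in seq_len(M)) {
    idx <- (m - 1L) * dh + seq_len(dh)
    logits <- (q[, idx, drop = FALSE] %*% t(k[, idx, drop = FALSE])) / sqrt(dh) +
      bias[, , m]
    out[, idx] <- softmax_rows(logits) %*% v[, idx, drop = FALSE]
  }
  linear_fwd(enc$wo, out)
}

#' Encoder layer forward over S5
#'
#' Flattens S5 to tokens, adds a 2D sinusoidal position embedding, applies
#' self-attention (standard or deformable per the config), then the
#' residual + layer-norm + feed-forward structure of a post-norm transformer
#' layer, and restores the S5 shape.
#'
#' @param enc encoder built by the model factory (with weights).
#' @param S5 array \[H, W, d_model\].
#' @return array of the same shape as `S5`.
#' @export
aifi_forward <- function(enc, S5) {
  cfg <- enc$cfg
  d <- dim(S5); H <- d[1]; W <- d[2]
  tok <- flatten_hw(S5)
  pos <- sine_pos_embed_2d(H, W, cfg$d_model)
  tok_p <- tok + pos
  attn <- if (cfg$mode == "dat") {
    dat_attention(enc, unflatten_hw(tok_p, H, W))
  } else {
    mhsa_tokens(enc, tok_p, tok_p)
  }
  x <- ln_fwd(enc$ln1, tok + attn)
  ff <- linear_fwd(enc$ffn2, act_fwd(linear_fwd(enc$ffn1, x), "gelu"))
  x <- ln_fwd(enc$ln2, x + ff)
  unflatten_hw(x, H, W)
}
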