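# Cross-scale feature fusion neck. Baseline topology ("ccfm"): top-down and
# bottom-up paths with 1x1 lateral convolutions, nearest-neighbour upsampling,
# stride-2 3x3 downsampling convolutions, and RepC3 fusion blocks. The
# "slimneck" variant swaps the lateral fusion convolutions for GSConv and the
# stride-16 bottom-up fusion block for VoVGSCSP; the "ssff" variant adds a
# scale-sequence fusion branch (levels projected to half width, resized to
# stride-8 resolution, stacked along a scale axis, fused by a 3D convolution
# over the scale axis, expanded back) injected into the high-resolution
# output path. "slimneck_ssff" enables both.

#' Neck configuration
#'
#' @param mode one of `"ccfm"`, `"slimneck"`, `"ssff"`, `"slimneck_ssff"`.
#' @param fused_width channel width of all fused maps.
#' @param repc3_depth RepConv count inside each RepC3 block.
#' @param repc3_expansion hidden-width expansion of RepC3.
#' @param vov_expansion hidden-width expansion of VoVGSCSP.
#' @param ssff_kernel scale-axis kernel depth of the SSFF 3D convolution.
#' @return list of class `neck_config`.
#' @export
neck_config <- function(mode = c("ccfm", "slimneck", "ssff", "slimneck_ssff"),
                        fused_width = 256L, repc3_depth = 3L,
                        repc3_expansion = 0.5, vov_expansion = 0.5,
                        ssff_kernel = 3L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, fused_width = as.integer(fused_width),
                 repc3_depth = as.integer(repc3_depth),
                 repc3_expansion = repc3_expansion,
                 vov_expansion = vov_expansion,
                 ssff_kernel = as.integer(ssff_kernel)),
            class = "neck_config")
}

#' Two-group channel shuffle
#'
#' The fixed permutation that interleaves the two halves of the channel axis
#' (reshape to 2 x c/2, transpose, flatten). `channel_shuffle_perm` returns
#' the permutation itself; applying the permutation of the inverse restores
#' the original order.
#'
#' @param c_total even channel count.
#' @return integer permutation of `1:c_total`.
#' @export
channel_shuffle_perm <- function(c_total) {
  stopifnot(c_total %% 2 == 0)
  as.vector(rbind(seq_len(c_total %/% 2), c_total %/% 2 + seq_len(c_total %/% 2)))
}

channel_shuffle <- function(x, perm = channel_shuffle_perm(dim(x)[3])) {
  x[, , perm, drop = FALSE]
}

# ---- GSConv family ----------------------------------------------------------

bld_gsconv <- function(prof, name, cin, cout, k, stride, hw, init) {
  if (cout %% 2 != 0) stop("gsconv: output channel count must be even")
  half <- cout %/% 2L
  obj <- list(kind = "gsconv")
  obj$cv1 <- bld_convbn(prof, paste0(name, ".cv1"), cin, half, k,
                        stride = stride, act = "silu", hw = hw, init = init)
  obj$cv2 <- bld_convbn(prof, paste0(name, ".dw"), half, half, 5,
                        groups = half, act = "silu", hw = obj$cv1$out_hw,
                        init = init)
  obj$perm <- channel_shuffle_perm(cout)
  obj$out_hw <- obj$cv1$out_hw
  obj
}

gsconv_fwd <- function(obj, x) {
  a <- convbn_fwd(obj$cv1, x)
  b <- convbn_fwd(obj$cv2, a)
  d <- dim(a)
  y <- array(0, c(d[1], d[2], 2L * d[3]))
  y[, , seq_len(d[3])] <- a
  y[, , d[3] + seq_len(d[3])] <- b
  channel_shuffle(y, obj$perm)
}

bld_gsbottleneck <- function(prof, name, c_io, hw, init) {
  obj <- list(kind = "gsbottleneck")
  obj$gs1 <- bld_gsconv(prof, paste0(name, ".gs1"), c_io, c_io, 1, 1, hw, init)
  obj$gs2 <- bld_gsconv(prof, paste0(name, ".gs2"), c_io, c_io, 3, 1, hw, init)
  obj$sc <- bld_convbn(prof, paste0(name, ".dwsc"), c_io, c_io, 3,
                       groups = c_io, act = "identity", hw = hw, init = init)
  obj$out_hw <- hw
  obj
}

gsbottleneck_fwd <- function(obj, x) {
  gsconv_fwd(obj$gs2, gsconv_fwd(obj$gs1, x)) + convbn_fwd(obj$sc, x)
}

bld_vovgscsp <- function(prof, name, cin, cout, n, expansion, hw, init) {
  ch <- as.integer(round(cout * expansion))
  if (ch %% 2 != 0) ch <- ch + 1L
  obj <- list(kind = "vovgscsp", n = n)
  obj$cv1 <- bld_convbn(prof, paste0(name, ".cv1"), cin, ch, 1,
                        act = "silu", hw = hw, init = init)
  obj$cv2 <- bld_convbn(prof, paste0(name, ".cv2"), cin, ch, 1,
                        act = "silu", hw = hw, init = init)
  obj$m <- lapply(seq_len(n), function(i)
    bld_gsbottleneck(prof, sprintf("%s.gsb%d", name, i), ch, hw, init))
  obj$cv3 <- bld_convbn(prof, paste0(name, ".cv3"), 2L * ch, cout, 1,
                        act = "silu", hw = hw, init = init)
  obj$out_hw <- hw
  obj
}

vovgscsp_fwd <- function(obj, x) {
  a <- convbn_fwd(obj$cv1, x)
  for (gsb in obj$m) a <- gsbottleneck_fwd(gsb, a)
  b <- convbn_fwd(obj$cv2, x)
  d <- dim(a)
  y <- array(0, c(d[1], d[2], 2L * d[3]))
  y[, , seq_len(d[3])] <- a
  y[, , d[3] + seq_len(d[3])] <- b
  convbn_fwd(obj$cv3, y)             # single ("one-off") aggregation
}

# ---- RepC3 (baseline fusion block) ------------------------------------------

bld_repconv <- function(prof, name, c_io, hw, init) {
  obj <- list(kind = "repconv")
  obj$k3 <- bld_convbn(prof, paste0(name, ".k3"), c_io, c_io, 3,
                       act = "identity", hw = hw, init = init)
  obj$k1 <- bld_convbn(prof, paste0(name, ".k1"), c_io, c_io, 1,
                       act = "identity", hw = hw, init = init)
  obj$out_hw <- hw
  obj
}

repconv_fwd <- function(obj, x) {
  act_fwd(convbn_fwd(obj$k3, x) + convbn_fwd(obj$k1, x), "silu")
}

bld_repc3 <- function(prof, name, cin, cout, n, expansion, hw, init) {
  ch <- as.integer(round(cout * expansion))
  obj <- list(kind = "repc3", n = n)
  obj$cv1 <- bld_convbn(prof, paste0(name, ".cv1"), cin, ch, 1,
                        act = "silu", hw = hw, init = init)
  obj$cv2 <- bld_convbn(prof, paste0(name, ".cv2"), cin, ch, 1,
                        act = "silu", hw = hw, init = init)
  obj$m <- lapply(seq_len(n), function(i)
    bld_repconv(prof, sprintf("%s.rep%d", name, i), ch, hw, init))
  obj$cv3 <- if (ch != cout) {
    bld_convbn(prof, paste0(name, ".cv3"), ch, cout, 1, act = "identity",
               hw = hw, init = init)
  }
  obj$out_hw <- hw
  obj
}

repc3_fwd <- function(obj, x) {
  a <- convbn_fwd(obj$cv1, x)
  for (rc in obj$m) a <- repconv_fwd(rc, a)
  y <- a + convbn_fwd(obj$cv2, x)
  if (!is.null(obj$cv3)) y <- convbn_fwd(obj$cv3, y) else y
}

# ---- SSFF -------------------------------------------------------------------

bld_ssff <- function(prof, name, width, kernel, hw, init) {
  # per-level 1x1 projections to half width, then a 3D convolution over the
  # scale axis (kernel x 1 x 1, valid over scale) collapsing the 3-level
  # stack to one stride-8 map, then a 1x1 expansion back to the fused width
  cm <- width %/% 2L
  obj <- list(kind = "ssff", width = width, cm = cm, kernel = kernel)
  obj$proj <- lapply(1:3, function(l)
    bld_convbn(prof, sprintf("%s.proj%d", name, l), width, cm, 1,
               act = "silu", hw = hw %/% (2L^(l - 1L)), init = init))
  prof_add(prof, paste0(name, ".conv3d"), "conv3d",
           kernel * cm * cm + cm, kernel * cm * cm * hw[1] * hw[2])
  prof_add(prof, paste0(name, ".bn3d"), "bn", 2 * cm, 0)
  obj$expand <- bld_convbn(prof, paste0(name, ".expand"), cm, width, 1,
                           act = "silu", hw = hw, init = init)
  if (init) {
    obj$w <- array(.winit(c(cm, kernel, cm), kernel * cm), c(cm, kernel, cm))
    obj$b <- numeric(cm)
    obj$bn <- nn_bn(cm, init = TRUE)
  }
  obj$out_hw <- hw
  obj
}

#' Scale-sequence feature fusion
#'
#' Projects each pyramid level to half width, resizes the stride-16 and
#' stride-32 maps to stride-8 resolution (nearest-neighbour, deterministic
#' and per-level), stacks the three maps along a new scale axis, fuses them
#' with a (kernel x 1 x 1) 3D convolution over the scale axis (valid,
#' collapsing to depth 1) followed by 3D batch-norm and SiLU, and expands
#' back to the fused width.
#'
#' @param obj ssff module built by the model factory (with weights).
#' @param P3,P4,P5 arrays with a common channel width at strides 8/16/32.
#' @return array with the shape of `P3`.
#' @export
ssff_fwd <- function(obj, P3, P4, P5) {
  C <- dim(P3)[3]
  if (dim(P4)[3] != C || dim(P5)[3] != C) stop("ssff: channel width mismatch")
  p3 <- convbn_fwd(obj$proj[[1]], P3)
  p4 <- convbn_fwd(obj$proj[[2]], P4)
  p5 <- convbn_fwd(obj$proj[[3]], P5)
  f4 <- dim(p3)[1] %/% dim(p4)[1]
  f5 <- dim(p3)[1] %/% dim(p5)[1]
  stack <- list(p3, upsample_nearest(p4, f4), upsample_nearest(p5, f5))
  d <- dim(p3)
  tok <- lapply(stack, flatten_hw)   # each [H*W, cm]
  out <- matrix(obj$b, d[1] * d[2], obj$cm, byrow = TRUE)
  for (s in seq_len(obj$kernel)) {   # valid conv over the scale axis
    out <- out + tok[[s]] %*% obj$w[, s, ]
  }
  y <- unflatten_hw(out, d[1], d[2])
  y <- act_fwd(bn_fwd(obj$bn, y), "silu")
  convbn_fwd(obj$expand, y)
}

# ---- full neck --------------------------------------------------------------

bld_lateral <- function(prof, name, cfg, width, hw, init) {
  if (cfg$mode %in% c("slimneck", "slimneck_ssff")) {
    bld_gsconv(prof, name, width, width, 1, 1, hw, init)
  } else {
    bld_convbn(prof, name, width, width, 1, act = "silu", hw = hw, init = init)
  }
}

lateral_fwd <- function(obj, x) {
  if (identical(obj$kind, "gsconv")) gsconv_fwd(obj, x) else convbn_fwd(obj, x)
}

#' Build the fusion neck
#'
#' @param cfg a [neck_config()].
#' @param hw3 spatial extent (h, w) of the stride-8 input map.
#' @param prof optional profile ledger.
#' @param init initialize weights.
#' @return neck object.
#' @export
build_neck <- function(cfg = neck_config(), hw3 = c(80L, 80L), prof = NULL,
                       init = FALSE) {
  w <- cfg$fused_width
  hw4 <- hw3 %/% 2L; hw5 <- hw3 %/% 4L
  slim <- cfg$mode %in% c("slimneck", "slimneck_ssff")
  nk <- list(cfg = cfg)
  nk$lat5 <- bld_lateral(prof, "neck.lat5", cfg, w, hw5, init)
  nk$fpn4 <- bld_repc3(prof, "neck.fpn4", 2L * w, w, cfg$repc3_depth,
                       cfg$repc3_expansion, hw4, init)
  nk$lat4 <- bld_lateral(prof, "neck.lat4", cfg, w, hw4, init)
  nk$fpn3 <- bld_repc3(prof, "neck.fpn3", 2L * w, w, cfg$repc3_depth,
                       cfg$repc3_expansion, hw3, init)
  nk$down3 <- bld_convbn(prof, "neck.down3", w, w, 3, stride = 2, act = "silu",
                         hw = hw3, init = init)
  nk$pan4 <- if (slim) {
    bld_vovgscsp(prof, "neck.pan4", 2L * w, w, 1L, cfg$vov_expansion, hw4, init)
  } else {
    bld_repc3(prof, "neck.pan4", 2L * w, w, cfg$repc3_depth,
              cfg$repc3_expansion, hw4, init)
  }
  nk$down4 <- bld_convbn(prof, "neck.down4", w, w, 3, stride = 2, act = "silu",
                         hw = hw4, init = init)
  nk$pan5 <- bld_repc3(prof, "neck.pan5", 2L * w, w, cfg$repc3_depth,
                       cfg$repc3_expansion, hw5, init)
  if (cfg$mode %in% c("ssff", "slimneck_ssff")) {
    nk$ssff <- bld_ssff(prof, "neck.ssff", w, cfg$ssff_kernel, hw3, init)
  }
  nk
}

concat_c <- function(a, b) {
  d <- dim(a)
  y <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  y[, , seq_len(d[3])] <- a
  y[, , d[3] + seq_len(dim(b)[3])] <- b
  y
}

#' Neck forward pass
#'
#' @param nk neck built with `init = TRUE`.
#' @param pyramid list with `S3`, `S4`, `S5` (S5 already encoder-processed),
#'   all at the fused width.
#' @return list with `P3`, `P4`, `P5` fused maps at strides 8/16/32.
#' @export
neck_forward <- function(nk, pyramid) {
  y5 <- lateral_fwd(nk$lat5, pyramid$S5)
  f4 <- repc3_fwd(nk$fpn4, concat_c(upsample_nearest(y5, 2L), pyramid$S4))
  y4 <- lateral_fwd(nk$lat4, f4)
  f3 <- repc3_fwd(nk$fpn3, concat_c(upsample_nearest(y4, 2L), pyramid$S3))
  d3 <- convbn_fwd(nk$down3, f3)
  in4 <- concat_c(d3, y4)
  f4b <- if (identical(nk$pan4$kind, "vovgscsp")) {
    vovgscsp_fwd(nk$pan4, in4)
  } else {
    repc3_fwd(nk$pan4, in4)
  }
  d4 <- convbn_fwd(nk$down4, f4b)
  f5b <- repc3_fwd(nk$pan5, concat_c(d4, y5))
  P3 <- f3
  if (!is.null(nk$ssff)) P3 <- P3 + ssff_fwd(nk$ssff, f3, f4b, f5b)
  list(P3 = P3, P4 = f4b, P5 = f5b)
}
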