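# ResNet-18-style feature extraction backbone (vd variant: three 3x3 stem
# convolutions, average-pool shortcuts) emitting the S3/S4/S5 pyramid at
# strides 8/16/32. Each of the four residual stages is switchable between the
# standard Basic_Block and the partial-convolution PConv_Block, in which the
# second 3x3 convolution of every block is replaced by a PConv over cp =
# round(ratio * c) channels (the substitution that preserves the block's
# channel count and residual topology).

#' Backbone configuration
#'
#' @param stage_types character vector of length 4 over `"basic"` / `"pconv"`.
#'   The lightweight default used by the full model is
#'   `c("basic", "pconv", "pconv", "pconv")` (last three stages swapped).
#' @param stage_channels channel widths of the four stages.
#' @param blocks_per_stage residual blocks per stage.
#' @param pconv_ratio fraction of channels convolved by PConv (cp = round(r*c)).
#' @param pconv_position `"first"` or `"last"` cp channels convolved.
#' @return list of class `backbone_config`.
#' @export
backbone_config <- function(stage_types = rep("basic", 4),
                            stage_channels = c(64L, 128L, 256L, 512L),
                            blocks_per_stage = c(2L, 2L, 2L, 2L),
                            pconv_ratio = 0.25,
                            pconv_position = "first") {
  stopifnot(length(stage_types) == 4, all(stage_types %in% c("basic", "pconv")),
            length(stage_channels) == 4, length(blocks_per_stage) == 4,
            pconv_ratio > 0, pconv_ratio <= 1)
  structure(list(stage_types = stage_types,
                 stage_channels = as.integer(stage_channels),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 pconv_ratio = pconv_ratio,
                 pconv_position = pconv_position),
            class = "backbone_config")
}

bld_basic_block <- function(prof, name, cin, cout, stride, type, ratio,
                            position, hw, init) {
  blk <- list(type = type, stride = stride)
  blk$conv1 <- bld_convbn(prof, paste0(name, ".conv1"), cin, cout, 3,
                          stride = stride, act = "relu", hw = hw, init = init)
  hw2 <- blk$conv1$out_hw
  if (type == "pconv") {
    blk$conv2 <- bld_pconvbn(prof, paste0(name, ".conv2"), cout, ratio,
                             position, hw2, act = "identity", init = init)
  } else {
    blk$conv2 <- bld_convbn(prof, paste0(name, ".conv2"), cout, cout, 3,
                            act = "identity", hw = hw2, init = init)
  }
  if (stride != 1 || cin != cout) {
    # vd shortcut: 2x2 average pool (when striding) then 1x1 conv
    blk$down <- bld_convbn(prof, paste0(name, ".down"), cin, cout, 1,
                           act = "identity", hw = hw %/% stride, init = init)
  }
  blk$out_hw <- hw2
  blk
}

basic_block_fwd <- function(blk, x) {
  y <- convbn_fwd(blk$conv1, x)
  y <- if (blk$type == "pconv") pconvbn_fwd(blk$conv2, y) else convbn_fwd(blk$conv2, y)
  sc <- x
  if (!is.null(blk$down)) {
    if (blk$stride != 1) sc <- avgpool2d(sc, 2, blk$stride)
    sc <- convbn_fwd(blk$down, sc)
  }
  act_fwd(y + sc, "relu")
}

#' Build the backbone
#'
#' @param cfg a [backbone_config()].
#' @param input_size input image side (must be divisible by 32).
#' @param prof optional profile ledger (internal).
#' @param init initialize weights (needed for [backbone_forward()]).
#' @return backbone object; submodule layers carry their accounting.
#' @export
build_backbone <- function(cfg = backbone_config(), input_size = 640,
                           prof = NULL, init = FALSE) {
  if (input_size %% 32 != 0) stop("input size must be divisible by 32")
  hw <- c(input_size, input_size)
  ch <- cfg$stage_channels
  stem_mid <- max(ch[1] %/% 2L, 4L)
  bb <- list(cfg = cfg)
  bb$stem1 <- bld_convbn(prof, "stem.conv1", 3, stem_mid, 3, stride = 2,
                         act = "relu", hw = hw, init = init)
  bb$stem2 <- bld_convbn(prof, "stem.conv2", stem_mid, stem_mid, 3,
                         act = "relu", hw = bb$stem1$out_hw, init = init)
  bb$stem3 <- bld_convbn(prof, "stem.conv3", stem_mid, ch[1], 3,
                         act = "relu", hw = bb$stem2$out_hw, init = init)
  hw <- bb$stem3$out_hw %/% 2L      # 3x3/2 max pool
  cin <- ch[1]
  bb$stages <- vector("list", 4)
  for (s in 1:4) {
    stride1 <- if (s == 1) 1L else 2L
    blocks <- vector("list", cfg$blocks_per_stage[s])
    for (b in seq_len(cfg$blocks_per_stage[s])) {
      nm <- sprintf("stage%d.block%d", s, b)
      blocks[[b]] <- bld_basic_block(prof, nm,
                                     cin = if (b == 1) cin else ch[s],
                                     cout = ch[s],
                                     stride = if (b == 1) stride1 else 1L,
                                     type = cfg$stage_types[s],
                                     ratio = cfg$pconv_ratio,
                                     position = cfg$pconv_position,
                                     hw = hw, init = init)
      hw <- blocks[[b]]$out_hw
    }
    bb$stages[[s]] <- blocks
    cin <- ch[s]
  }
  bb$out_channels <- ch[2:4]
  bb
}

#' Backbone forward pass
#'
#' @param bb backbone built with `init = TRUE`.
#' @param image array \[H, W, 3\], H and W divisible by 32.
#' @return list with `S3`, `S4`, `S5` feature maps at strides 8/16/32.
#' @export
backbone_forward <- function(bb, image) {
  d <- dim(image)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop("backbone_forward: image sides must be divisible by 32")
  }
  x <- convbn_fwd(bb$stem1, image)
  x <- convbn_fwd(bb$stem2, x)
  x <- convbn_fwd(bb$stem3, x)
  x <- maxpool2d(x, 3, 2, 1)
  outs <- vector("list", 4)
  for (s in 1:4) {
    for (blk in bb$stages[[s]]) x <- basic_block_fwd(blk, x)
    outs[[s]] <- x
  }
  list(S3 = outs[[2]], S4 = outs[[3]], S5 = outs[[4]])
}
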