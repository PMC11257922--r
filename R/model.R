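# Model factory: assembles backbone, input projections, intra-scale encoder,
# fusion neck and decoder head from a single configuration, the four
# lightweighting switches mapping 1:1 to config flags:
#   pconv_block   -> PConv_Block in the last three backbone stages
#   aifi_dat      -> deformable attention in the S5 encoder layer
#   slimneck_ssff -> GSConv/VoVGSCSP slim-neck plus scale-sequence fusion
#   inner_eiou    -> Inner-EIoU box regression loss (ratio 0.7)

#' Model configuration (the ablation switchboard)
#'
#' The four switches reproduce the ablation family; individual submodule
#' configs can be overridden for finer control (e.g. the four neck modes).
#' `preset = "smoke"` builds a width-reduced model for CPU-scale training
#' experiments (stage widths 16-128, decoder width 64, 40 queries, 320 px).
#'
#' @param pconv_block,aifi_dat,slimneck_ssff,inner_eiou the ablation switches.
#' @param num_classes number of ripeness classes.
#' @param image_size input side used for profiling and training.
#' @param preset `"full"` (profiling-scale) or `"smoke"` (training-scale).
#' @param backbone,encoder,neck,head,loss optional submodule config overrides.
#' @return list of class `model_config`.
#' @export
model_config <- function(pconv_block = FALSE, aifi_dat = FALSE,
                         slimneck_ssff = FALSE, inner_eiou = FALSE,
                         num_classes = 5L, image_size = 640L,
                         preset = c("full", "smoke"),
                         backbone = NULL, encoder = NULL, neck = NULL,
                         head = NULL, loss = NULL) {
  preset <- match.arg(preset)
  if (preset == "smoke") {
    image_size <- 320L
    backbone <- backbone %||% backbone_config(stage_channels = c(16L, 32L, 64L, 128L))
    encoder <- encoder %||% encoder_config(d_model = 64L, heads = 4L, ffn_dim = 128L)
    neck <- neck %||% neck_config(fused_width = 64L, repc3_depth = 1L)
    head <- head %||% head_config(n_queries = 40L, dec_layers = 1L,
                                  d_model = 64L, heads = 4L, points = 2L,
                                  ffn_dim = 128L, dn_groups = 2L)
  }
  backbone <- backbone %||% backbone_config()
  encoder <- encoder %||% encoder_config()
  neck <- neck %||% neck_config()
  head <- head %||% head_config()
  loss <- loss %||% loss_config()
  if (pconv_block) backbone$stage_types <- c("basic", "pconv", "pconv", "pconv")
  if (aifi_dat) encoder$mode <- "dat"
  if (slimneck_ssff) neck$mode <- "slimneck_ssff"
  if (inner_eiou) loss$box <- "inner_eiou"
  stopifnot(neck$fused_width == encoder$d_model,
            head$d_model == encoder$d_model)
  structure(list(switches = c(pconv_block = pconv_block, aifi_dat = aifi_dat,
                              slimneck_ssff = slimneck_ssff,
                              inner_eiou = inner_eiou),
                 num_classes = as.integer(num_classes),
                 image_size = as.integer(image_size), preset = preset,
                 backbone = backbone, encoder = encoder, neck = neck,
                 head = head, loss = loss),
            class = "model_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a model from a configuration
#'
#' With `init = FALSE` only the architecture (shapes and accounting) is
#' materialized — enough for profiling. With `init = TRUE` all weights are
#' initialized from the given seed, enabling forward passes.
#'
#' @param cfg a [model_config()].
#' @param init initialize weights.
#' @param seed RNG seed used for weight initialization.
#' @return model object with a per-layer `profile` data.frame.
#' @export
build_model <- function(cfg = model_config(), init = FALSE, seed = 1L) {
  if (cfg$image_size %% 32 != 0) stop("image_size must be divisible by 32")
  if (init) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  prof <- new_profile()
  d <- cfg$encoder$d_model
  m <- list(cfg = cfg)
  m$backbone <- build_backbone(cfg$backbone, cfg$image_size, prof, init)
  hw3 <- c(cfg$image_size %/% 8L, cfg$image_size %/% 8L)
  hw4 <- hw3 %/% 2L; hw5 <- hw3 %/% 4L
  oc <- m$backbone$out_channels
  m$proj3 <- bld_convbn(prof, "proj.S3", oc[1], d, 1, act = "identity",
                        hw = hw3, init = init)
  m$proj4 <- bld_convbn(prof, "proj.S4", oc[2], d, 1, act = "identity",
                        hw = hw4, init = init)
  m$proj5 <- bld_convbn(prof, "proj.S5", oc[3], d, 1, act = "identity",
                        hw = hw5, init = init)
  m$encoder <- build_aifi(cfg$encoder, hw5, prof, init)
  m$neck <- build_neck(cfg$neck, hw3, prof, init)
  m$decoder <- build_decoder(cfg$head, cfg$num_classes,
                             list(hw3, hw4, hw5), prof, init)
  m$profile <- prof_table(prof)
  m$input_size <- cfg$image_size
  m
}

#' Full model forward pass
#'
#' @param model model built with `init = TRUE`.
#' @param image array \[H, W, 3\] with values in \[0, 1\], sides divisible by 32.
#' @param dn optional denoising fragment (training).
#' @param aux keep per-layer auxiliary outputs (training).
#' @return see [decode()]; `$detections` is the scored detection set.
#' @export
model_forward <- function(model, image, dn = NULL, aux = FALSE) {
  py <- backbone_forward(model$backbone, image)
  S3 <- convbn_fwd(model$proj3, py$S3)
  S4 <- convbn_fwd(model$proj4, py$S4)
  S5 <- convbn_fwd(model$proj5, py$S5)
  F5 <- aifi_forward(model$encoder, S5)
  fused <- neck_forward(model$neck, list(S3 = S3, S4 = S4, S5 = F5))
  decode(model$decoder, fused, image_size = dim(image)[1], dn = dn, aux = aux)
}
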