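# Deterministic parameter and FLOP accounting. The counting convention is
# frozen across every configuration: one fused multiply-add = 2 FLOPs;
# convolutions, linear maps and attention matrix products are counted;
# normalization, activation, resize, softmax and pooling are excluded;
# partial convolutions are counted as h*w*k^2*cp^2 MACs with pass-through
# channels free.

.known_kinds <- c("conv2d", "pconv", "bn", "ln", "linear", "attention",
                  "embedding", "conv3d")

#' Count trainable parameters of a built model
#'
#' @param model result of [build_model()].
#' @return integer: number of trainable scalar weights.
#' @export
count_params <- function(model) {
  .check_kinds(model$profile)
  sum(model$profile$params)
}

.check_kinds <- function(tab) {
  bad <- setdiff(unique(tab$kind), .known_kinds)
  if (length(bad)) stop("uncounted layer kind(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Profile a built model: per-layer accounting and totals
#'
#' @param model result of [build_model()].
#' @return list of class `profile_report`: `layers` (per-layer data.frame),
#'   `total_params`, `params_m` (millions), `total_macs`, `gflops`
#'   (2 x MACs / 1e9 at the model's input size), `input_size`.
#' @export
count_flops <- function(model) {
  tab <- model$profile
  .check_kinds(tab)
  structure(list(layers = tab,
                 total_params = sum(tab$params),
                 params_m = sum(tab$params) / 1e6,
                 total_macs = sum(tab$macs),
                 gflops = 2 * sum(tab$macs) / 1e9,
                 input_size = model$input_size),
            class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("profile at %dx%d: %.2f M params, %.1f GFLOPs (%d layers)\n",
              x$input_size, x$input_size, x$params_m, x$gflops,
              nrow(x$layers)))
  invisible(x)
}

#' Profile a model configuration without materializing weights
#'
#' @param cfg a [model_config()].
#' @return a `profile_report`.
#' @export
profile_model <- function(cfg = model_config()) {
  count_flops(build_model(cfg, init = FALSE))
}

#' Profile a list of configurations into an ablation table
#'
#' @param configs named list of [model_config()]s.
#' @param file optional path: writes the table as CSV.
#' @return data.frame with one row per configuration: the four switch states,
#'   `params_m` and `gflops`.
#' @export
ablation_table <- function(configs, file = NULL) {
  rows <- lapply(names(configs), function(nm) {
    cfg <- configs[[nm]]
    pr <- profile_model(cfg)
    data.frame(config = nm,
               pconv_block = cfg$switches[["pconv_block"]],
               aifi_dat = cfg$switches[["aifi_dat"]],
               slimneck_ssff = cfg$switches[["slimneck_ssff"]],
               inner_eiou = cfg$switches[["inner_eiou"]],
               params_m = round(pr$params_m, 2),
               gflops = round(pr$gflops, 1))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
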