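# Reproducible entry points driven by a single configuration: generate a
# synthetic dataset, train (head-training path), evaluate, profile. Every
# run writes its resolved configuration and seed next to its outputs, so any
# artifact on disk is reconstructible from config + seed.

#' Build a run configuration
#'
#' Training defaults follow the reference setup: batch size 4, 100 epochs,
#' learning rate 1e-4, 640 x 640 input. The `"smoke"` preset is the CPU
#' pipeline check: 16 synthetic scenes at 320 x 320, 300 head-training steps
#' on a width-reduced model.
#'
#' @param preset `"default"` or `"smoke"`.
#' @param ... overrides of any top-level or nested field (named lists merge).
#' @return nested configuration list of class `ripedetr_config`.
#' @export
ripedetr_config <- function(preset = c("default", "smoke"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    seed = 1L,
    model = list(pconv_block = FALSE, aifi_dat = FALSE, slimneck_ssff = FALSE,
                 inner_eiou = FALSE),
    train = list(batch_size = 4L, epochs = 100L, learning_rate = 1e-4,
                 image_size = 640L, steps = NA_integer_, head_lr = 5e-3),
    loss = list(box = "giou", inner_ratio = 0.7),
    data = list(n_images = 64L, n_fruits = 6L, occlusion_prob = 0.3,
                format = "coco_json", augment_prob = 0.5,
                split = c(0.70, 0.10, 0.20))
  )
  if (preset == "smoke") {
    cfg$train$image_size <- 320L
    cfg$train$steps <- 300L
    cfg$data$n_images <- 16L
    cfg$data$n_fruits <- 3L
  }
  overrides <- list(...)
  merge_in <- function(base, ov) {
    for (nm in names(ov)) {
      base[[nm]] <- if (is.list(ov[[nm]]) && is.list(base[[nm]])) {
        merge_in(base[[nm]], ov[[nm]])
      } else ov[[nm]]
    }
    base
  }
  structure(merge_in(cfg, overrides), class = "ripedetr_config")
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file.
#' @return for `read_config`, a `ripedetr_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  preset <- raw$preset %||% "default"
  do.call(ripedetr_config,
          c(list(preset = preset), raw[setdiff(names(raw), "preset")]))
}

#' @rdname read_config
#' @param cfg configuration to write.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.model_cfg_of <- function(cfg) {
  model_config(pconv_block = isTRUE(cfg$model$pconv_block),
               aifi_dat = isTRUE(cfg$model$aifi_dat),
               slimneck_ssff = isTRUE(cfg$model$slimneck_ssff),
               inner_eiou = isTRUE(cfg$model$inner_eiou),
               preset = if (cfg$preset == "smoke") "smoke" else "full",
               loss = loss_config(box = if (isTRUE(cfg$model$inner_eiou))
                 "inner_eiou" else cfg$loss$box,
                 inner_ratio = cfg$loss$inner_ratio))
}

.log_run <- function(cfg, out_dir, extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(cfg, file.path(out_dir, "resolved_config.yaml"))
  jsonlite::write_json(c(list(seed = cfg$seed, time = format(Sys.time())),
                         extra),
                       file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
}

.scenes_for <- function(cfg) {
  n <- cfg$data$n_images
  lapply(seq_len(n), function(i) {
    generate_scene(scene_spec(image_size = cfg$train$image_size,
                              n_fruits = cfg$data$n_fruits,
                              occlusion_prob = cfg$data$occlusion_prob,
                              seed = cfg$seed * 10000L + i))
  })
}

#' Generate a dataset on disk
#'
#' Renders scenes (optionally augmenting a per-sample random subset with one
#' of the three augmentation ops), splits them 70/10/20, and writes images
#' plus annotations and a manifest.
#'
#' @param cfg a [ripedetr_config()].
#' @param out_dir output directory.
#' @return the manifest.
#' @export
run_generate <- function(cfg = ripedetr_config(), out_dir) {
  scenes <- .scenes_for(cfg)
  ops <- c("mean_blur", "random_crop", "random_rotate")
  samples <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    set.seed(cfg$seed * 20000L + i)
    if (stats::runif(1) < cfg$data$augment_prob) {
      a <- augment(sc$image, sc$boxes, sample(ops, 1),
                   seed = cfg$seed * 30000L + i,
                   out_size = cfg$train$image_size)
      sc$image <- a$image; sc$boxes <- a$boxes
    }
    list(id = sprintf("scene_%04d", i), image = sc$image, boxes = sc$boxes,
         size = cfg$train$image_size)
  })
  split <- split_dataset(length(samples), cfg$data$split, seed = cfg$seed)
  man <- write_dataset(samples, cfg$data$format, out_dir, split = split)
  .log_run(cfg, out_dir, list(n_images = length(samples)))
  man
}

#' Train the detection heads on synthetic scenes
#'
#' @param cfg a [ripedetr_config()] (use the `"smoke"` preset for CPU scale).
#' @param out_dir optional directory for the loss curve and resolved config.
#' @return list with `model`, `loss_curve`, `scenes`.
#' @export
run_train <- function(cfg = ripedetr_config("smoke"), out_dir = NULL) {
  steps <- cfg$train$steps
  if (is.na(steps)) steps <- 300L
  model <- build_model(.model_cfg_of(cfg), init = TRUE, seed = cfg$seed)
  scenes <- .scenes_for(cfg)
  res <- train_heads(model, scenes, steps = steps, lr = cfg$train$head_lr)
  if (!is.null(out_dir)) {
    .log_run(cfg, out_dir,
             list(steps = steps,
                  loss_first = res$loss_curve[1],
                  loss_last = res$loss_curve[steps]))
    jsonlite::write_json(res$loss_curve, file.path(out_dir, "loss_curve.json"),
                         digits = NA)
  }
  c(res, list(scenes = scenes))
}

#' Evaluate a model on scenes
#'
#' @param model trained model.
#' @param scenes list of scenes (ground truth from the generator).
#' @param conf_min detections below this confidence are discarded first.
#' @return an evaluation report, see [map_suite()].
#' @export
run_eval <- function(model, scenes, conf_min = 0.05) {
  dets <- lapply(scenes, function(sc) {
    d <- model_forward(model, sc$image)$detections
    d[d$conf >= conf_min, , drop = FALSE]
  })
  gts <- lapply(scenes, function(sc) sc$boxes)
  map_suite(dets, gts)
}

#' Profile a configuration
#'
#' @param cfg a [ripedetr_config()].
#' @param out optional JSON path for the report.
#' @return a `profile_report` for the configured model at 640 x 640
#'   (or the preset's size).
#' @export
run_profile <- function(cfg = ripedetr_config(), out = NULL) {
  pr <- profile_model(.model_cfg_of(cfg))
  if (!is.null(out)) {
    jsonlite::write_json(list(params = pr$total_params,
                              params_m = pr$params_m, gflops = pr$gflops,
                              input_size = pr$input_size),
                         out, auto_unbox = TRUE, digits = NA)
  }
  pr
}
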