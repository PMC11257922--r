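# CPU-scale training path. The feature pipeline (backbone, encoder, neck,
# decoder attention stack) is frozen at its seeded initialization and run
# once per image; the final decoder layer's classification head and box-
# refinement MLP are then optimized with analytic gradients (Adam) against
# the set-prediction loss. This exercises the full loss mathematics —
# Hungarian matching, IoU-weighted classification, L1 and the configured
# IoU-family box loss with its analytic gradient — at desk scale.

.adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.vfl_grad <- function(p, target, alpha = 0.75, gamma = 2) {
  # d(varifocal)/dlogit for matrix p = sigmoid(logit) and quality targets
  g <- matrix(0, nrow(p), ncol(p))
  pos <- target > 0
  g[pos] <- p[pos] - target[pos]
  pn <- p[!pos]
  eps <- 1e-9
  g[!pos] <- -alpha * (gamma * pn^(gamma - 1) * log(1 - pn + eps) * pn * (1 - pn) -
                         pn^(gamma + 1))
  g
}

.box_grad_fn <- function(loss_cfg) {
  switch(loss_cfg$box,
         giou = function(p, g) giou_grad(p, g),
         eiou = function(p, g) eiou_grad(p, g),
         inner_eiou = function(p, g) inner_eiou_grad(p, g, loss_cfg$inner_ratio))
}

# loss and gradients w.r.t. class logits and predicted boxes (cxcywh) for one
# image, under Hungarian matching (matching treated as fixed at the current
# predictions, targets detached — the standard DETR treatment)
matching_loss_grad <- function(logits, boxes, t_boxes, t_classes, loss_cfg) {
  nq <- nrow(boxes); S <- ncol(logits)
  w <- loss_cfg$weights
  p <- 1 / (1 + exp(-logits))
  if (nrow(t_boxes) == 0) {
    target <- matrix(0, nq, S)
    loss <- w[1] * sum(.varifocal_terms(p, target)) / max(nq, 1)
    return(list(loss = loss,
                g_logits = w[1] * .vfl_grad(p, target) / max(nq, 1),
                g_boxes = matrix(0, nq, 4)))
  }
  cost <- .match_cost(logits, boxes, t_boxes, t_classes,
                      w = loss_cfg$match_weights)
  pairs <- hungarian_match(cost)$pairs
  np <- nrow(pairs)
  pred_m <- boxes[pairs[, 1], , drop = FALSE]
  gt_m <- t_boxes[pairs[, 2], , drop = FALSE]
  qual <- iou(box_cxcywh_to_xyxy(pred_m), box_cxcywh_to_xyxy(gt_m))
  target <- matrix(0, nq, S)
  target[cbind(pairs[, 1], t_classes[pairs[, 2]] + 1L)] <- pmax(qual, 1e-3)

  cls <- sum(.varifocal_terms(p, target)) / np
  g_logits <- w[1] * .vfl_grad(p, target) / np

  l1 <- sum(abs(pred_m - gt_m)) / np
  g_boxes <- matrix(0, nq, 4)
  g_boxes[pairs[, 1], ] <- w[2] * sign(pred_m - gt_m) / np

  bgf <- .box_grad_fn(loss_cfg)
  box_l <- 0
  for (r in seq_len(np)) {
    bg <- bgf(pred_m[r, ], gt_m[r, ])
    box_l <- box_l + bg$loss
    g_boxes[pairs[r, 1], ] <- g_boxes[pairs[r, 1], ] + w[3] * bg$grad / np
  }
  box_l <- box_l / np

  list(loss = w[1] * cls + w[2] * l1 + w[3] * box_l,
       g_logits = g_logits, g_boxes = g_boxes)
}

#' Train the detection heads on a set of scenes
#'
#' Runs the frozen feature pipeline once per scene, caches the final decoder
#' embeddings and reference boxes, and optimizes the final classification
#' head and box-refinement MLP with Adam over `steps` full-batch iterations.
#' The trained weights are written back into the model.
#'
#' @param model model built with `init = TRUE`.
#' @param scenes list of scenes from [generate_scene()] (image sides must
#'   match the model's expectations: divisible by 32).
#' @param steps optimizer steps.
#' @param lr Adam learning rate.
#' @param loss_cfg a [loss_config()]; defaults to the model's.
#' @return list with `model` (updated), `loss_curve` (length `steps`), and
#'   `cached` features (internal reuse).
#' @export
train_heads <- function(model, scenes, steps = 300, lr = 5e-3,
                        loss_cfg = NULL) {
  loss_cfg <- loss_cfg %||% model$cfg$loss
  fl <- model$decoder$layers[[length(model$decoder$layers)]]

  cache <- lapply(scenes, function(sc) {
    out <- model_forward(model, sc$image, aux = FALSE)
    fin <- out$layers[[length(out$layers)]]
    sz <- dim(sc$image)[1]
    b <- sc$boxes
    t_boxes <- cbind((b$x1 + b$x2) / 2, (b$y1 + b$y2) / 2,
                     pmax(b$x2 - b$x1, 1), pmax(b$y2 - b$y1, 1)) / sz
    list(E = fin$embed, base_logit = .inv_sigmoid(fin$ref_in),
         t_boxes = t_boxes, t_classes = b$cls)
  })

  # trainable parameters: class head + 3-layer box MLP of the final layer
  params <- list(W = fl$cls_head$w, bW = fl$cls_head$b,
                 A1 = fl$bbox_head[[1]]$w, a1 = fl$bbox_head[[1]]$b,
                 A2 = fl$bbox_head[[2]]$w, a2 = fl$bbox_head[[2]]$b,
                 A3 = fl$bbox_head[[3]]$w, a3 = fl$bbox_head[[3]]$b)
  st <- .adam_new(params)
  curve <- numeric(steps)

  for (it in seq_len(steps)) {
    grads <- lapply(params, function(p) p * 0)
    tot <- 0
    for (ci in seq_along(cache)) {
      cc <- cache[[ci]]
      E <- cc$E
      logits <- sweep(E %*% params$W, 2, params$bW, "+")
      z1 <- sweep(E %*% params$A1, 2, params$a1, "+"); h1 <- pmax(z1, 0)
      z2 <- sweep(h1 %*% params$A2, 2, params$a2, "+"); h2 <- pmax(z2, 0)
      delta <- sweep(h2 %*% params$A3, 2, params$a3, "+")
      zbox <- cc$base_logit + delta
      boxes <- 1 / (1 + exp(-zbox))

      lg <- matching_loss_grad(logits, boxes, cc$t_boxes, cc$t_classes,
                               loss_cfg)
      tot <- tot + lg$loss

      grads$W <- grads$W + t(E) %*% lg$g_logits
      grads$bW <- grads$bW + colSums(lg$g_logits)
      g_delta <- lg$g_boxes * boxes * (1 - boxes)
      grads$A3 <- grads$A3 + t(h2) %*% g_delta
      grads$a3 <- grads$a3 + colSums(g_delta)
      g_h2 <- (g_delta %*% t(params$A3)) * (z2 > 0)
      grads$A2 <- grads$A2 + t(h1) %*% g_h2
      grads$a2 <- grads$a2 + colSums(g_h2)
      g_h1 <- (g_h2 %*% t(params$A2)) * (z1 > 0)
      grads$A1 <- grads$A1 + t(E) %*% g_h1
      grads$a1 <- grads$a1 + colSums(g_h1)
    }
    n <- length(cache)
    grads <- lapply(grads, function(g) g / n)
    curve[it] <- tot / n
    upd <- .adam_step(params, grads, st, lr)
    params <- upd$params; st <- upd$state
  }

  fl$cls_head$w <- params$W; fl$cls_head$b <- params$bW
  fl$bbox_head[[1]]$w <- params$A1; fl$bbox_head[[1]]$b <- params$a1
  fl$bbox_head[[2]]$w <- params$A2; fl$bbox_head[[2]]$b <- params$a2
  fl$bbox_head[[3]]$w <- params$A3; fl$bbox_head[[3]]$b <- params$a3
  model$decoder$layers[[length(model$decoder$layers)]] <- fl

  list(model = model, loss_curve = curve)
}
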