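# RT-DETR-style decoding stack: IoU-aware query selection from encoder
# tokens, optional denoising query groups during training, an iterative
# decoder whose layers refine reference boxes in sigmoid space via
# multi-scale deformable cross-attention, and the set-prediction loss
# (classification + L1 + an IoU-family box loss) with Hungarian matching.
# No non-maximum suppression: the decoder predicts a set directly.

#' Head configuration
#'
#' @param n_queries number of object queries selected from encoder tokens.
#' @param dec_layers decoder depth.
#' @param d_model decoder width.
#' @param heads attention heads.
#' @param points deformable sampling points per head and level.
#' @param ffn_dim feed-forward width.
#' @param dn_groups denoising groups used at training time.
#' @param dn_noise denoising box-noise scale.
#' @return list of class `head_config`.
#' @export
head_config <- function(n_queries = 300L, dec_layers = 3L, d_model = 256L,
                        heads = 8L, points = 4L, ffn_dim = 1024L,
                        dn_groups = 5L, dn_noise = 0.4) {
  stopifnot(d_model %% heads == 0)
  structure(list(n_queries = as.integer(n_queries),
                 dec_layers = as.integer(dec_layers),
                 d_model = as.integer(d_model), heads = as.integer(heads),
                 points = as.integer(points), ffn_dim = as.integer(ffn_dim),
                 dn_groups = as.integer(dn_groups), dn_noise = dn_noise),
            class = "head_config")
}

bld_mlp <- function(prof, name, dims, tokens, init) {
  lapply(seq_len(length(dims) - 1L), function(i)
    bld_linear(prof, sprintf("%s.fc%d", name, i), dims[i], dims[i + 1L],
               tokens, init = init))
}

mlp_fwd <- function(mlp, x, act = "relu") {
  n <- length(mlp)
  for (i in seq_len(n)) {
    x <- linear_fwd(mlp[[i]], x)
    if (i < n) x <- act_fwd(x, act)
  }
  x
}

bld_mha <- function(prof, name, d, heads, n_q, n_kv, init) {
  obj <- list(d = d, heads = heads)
  obj$wq <- bld_linear(prof, paste0(name, ".q"), d, d, n_q, init = init)
  obj$wk <- bld_linear(prof, paste0(name, ".k"), d, d, n_kv, init = init)
  obj$wv <- bld_linear(prof, paste0(name, ".v"), d, d, n_kv, init = init)
  obj$wo <- bld_linear(prof, paste0(name, ".o"), d, d, n_q, init = init)
  prof_add(prof, paste0(name, ".matmul"), "attention", 0, 2 * n_q * n_kv * d)
  obj
}

mha_fwd <- function(obj, q_in, k_in, v_in, mask = NULL) {
  M <- obj$heads; dh <- obj$d %/% M
  q <- linear_fwd(obj$wq, q_in)
  k <- linear_fwd(obj$wk, k_in)
  v <- linear_fwd(obj$wv, v_in)
  out <- matrix(0, nrow(q_in), obj$d)
  for (m in seq_len(M)) {
    idx <- (m - 1L) * dh + seq_len(dh)
    logits <- (q[, idx, drop = FALSE] %*% t(k[, idx, drop = FALSE])) / sqrt(dh)
    if (!is.null(mask)) logits[mask] <- -1e9
    out[, idx] <- softmax_rows(logits) %*% v[, idx, drop = FALSE]
  }
  linear_fwd(obj$wo, out)
}

#' Build the decoder head
#'
#' @param cfg a [head_config()].
#' @param num_classes object classes (background is implicit).
#' @param level_hw list of three (h, w) pairs for the fused pyramid levels.
#' @param prof optional profile ledger.
#' @param init initialize weights.
#' @return decoder object.
#' @export
build_decoder <- function(cfg = head_config(), num_classes = 5L,
                          level_hw, prof = NULL, init = FALSE) {
  d <- cfg$d_model
  n_mem <- sum(vapply(level_hw, prod, numeric(1)))
  nq <- cfg$n_queries
  dec <- list(cfg = cfg, num_classes = as.integer(num_classes))
  dec$enc_output <- bld_linear(prof, "dec.enc_output", d, d, n_mem, init = init)
  dec$enc_ln <- bld_ln(prof, "dec.enc_ln", d, init = init)
  dec$enc_score <- bld_linear(prof, "dec.enc_score", d, num_classes, n_mem,
                              init = init)
  dec$enc_bbox <- bld_mlp(prof, "dec.enc_bbox", c(d, d, d, 4L), nq, init)
  dec$query_pos <- bld_mlp(prof, "dec.query_pos", c(4L, d, d), nq, init)
  prof_add(prof, "dec.dn_label_embed", "embedding", (num_classes + 1L) * d, 0)
  if (init) {
    dec$dn_label_embed <- matrix(stats::rnorm((num_classes + 1L) * d, sd = 0.02),
                                 num_classes + 1L, d)
  }
  L <- 3L; M <- cfg$heads; P <- cfg$points
  dec$layers <- lapply(seq_len(cfg$dec_layers), function(li) {
    nm <- sprintf("dec.layer%d", li)
    ly <- list()
    ly$self_attn <- bld_mha(prof, paste0(nm, ".self"), d, M, nq, nq, init)
    ly$offsets <- bld_linear(prof, paste0(nm, ".cross.offsets"), d,
                             M * L * P * 2L, nq, init = init)
    ly$weights <- bld_linear(prof, paste0(nm, ".cross.weights"), d,
                             M * L * P, nq, init = init)
    ly$value_proj <- bld_linear(prof, paste0(nm, ".cross.value"), d, d, n_mem,
                                init = init)
    ly$out_proj <- bld_linear(prof, paste0(nm, ".cross.out"), d, d, nq,
                              init = init)
    prof_add(prof, paste0(nm, ".cross.agg"), "attention", 0, nq * M * L * P * (d %/% M))
    ly$ln1 <- bld_ln(prof, paste0(nm, ".ln1"), d, init = init)
    ly$ln2 <- bld_ln(prof, paste0(nm, ".ln2"), d, init = init)
    ly$ffn1 <- bld_linear(prof, paste0(nm, ".ffn.fc1"), d, cfg$ffn_dim, nq,
                          init = init)
    ly$ffn2 <- bld_linear(prof, paste0(nm, ".ffn.fc2"), cfg$ffn_dim, d, nq,
                          init = init)
    ly$ln3 <- bld_ln(prof, paste0(nm, ".ln3"), d, init = init)
    ly$cls_head <- bld_linear(prof, paste0(nm, ".cls_head"), d, num_classes,
                              nq, init = init)
    ly$bbox_head <- bld_mlp(prof, paste0(nm, ".bbox_head"), c(d, d, d, 4L),
                            nq, init)
    ly
  })
  dec
}

#' IoU-aware top-K query selection
#'
#' Selects the K tokens with the highest selection score (maximum class
#' probability per token). Ties are broken by token index, so the selection
#' is invariant to any reordering that is undone before ranking.
#'
#' @param class_logits n_tokens x S matrix of per-class logits.
#' @param K number of queries to select.
#' @return integer vector of K token indices in decreasing score order.
#' @export
select_queries <- function(class_logits, K) {
  n <- nrow(class_logits)
  if (K > n) stop("select_queries: K exceeds the token count")
  score <- apply(class_logits, 1, max)
  order(-score, seq_len(n))[seq_len(K)]
}

.inv_sigmoid <- function(p, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Denoising query fragment
#'
#' Builds `n_groups` groups of jittered ground-truth queries: each group has
#' one positive query per object (box noise bounded by `noise_scale`, true
#' label) and one negative (larger jitter, label flipped to a different
#' class). The attention mask blocks all attention across groups and both
#' directions between denoising and matching queries.
#'
#' @param gt_boxes n_gt x 4 matrix (normalized cxcywh).
#' @param gt_classes 0-based class ids.
#' @param n_groups number of denoising groups.
#' @param noise_scale box jitter bound (fraction of box size).
#' @param num_classes number of object classes.
#' @param n_match number of matching queries (for the mask).
#' @return list with `boxes`, `classes` (label id fed to the embedding),
#'   `gt_index`, `positive`, and logical `mask` of size
#'   (n_dn + n_match)^2 (TRUE = blocked), plus `n_dn`.
#' @export
denoising_queries <- function(gt_boxes, gt_classes, n_groups = 5L,
                              noise_scale = 0.4, num_classes = 5L,
                              n_match = 300L) {
  stopifnot(nrow(gt_boxes) >= 1)
  n_gt <- nrow(gt_boxes)
  per_group <- 2L * n_gt
  n_dn <- n_groups * per_group
  boxes <- matrix(0, n_dn, 4)
  classes <- integer(n_dn)
  gt_index <- integer(n_dn)
  positive <- logical(n_dn)
  row <- 0L
  for (g in seq_len(n_groups)) {
    for (i in seq_len(n_gt)) {
      for (neg in c(FALSE, TRUE)) {
        row <- row + 1L
        s <- if (neg) stats::runif(1, 1, 2) * noise_scale else noise_scale
        b <- gt_boxes[i, ]
        jit <- stats::runif(4, -s, s)
        b[1] <- b[1] + jit[1] * b[3] / 2
        b[2] <- b[2] + jit[2] * b[4] / 2
        b[3] <- b[3] * (1 + jit[3])
        b[4] <- b[4] * (1 + jit[4])
        boxes[row, ] <- pmin(pmax(b, 1e-4), 1)
        classes[row] <- if (neg) {
          sample(setdiff(seq_len(num_classes) - 1L, gt_classes[i]), 1L)
        } else gt_classes[i]
        gt_index[row] <- i
        positive[row] <- !neg
      }
    }
  }
  n_tot <- n_dn + n_match
  mask <- matrix(FALSE, n_tot, n_tot)
  for (g in seq_len(n_groups)) {
    rows <- (g - 1L) * per_group + seq_len(per_group)
    mask[rows, seq_len(n_dn)[-rows]] <- TRUE       # other groups blocked
  }
  mask[seq_len(n_dn), n_dn + seq_len(n_match)] <- TRUE  # dn -> match blocked
  mask[n_dn + seq_len(n_match), seq_len(n_dn)] <- TRUE  # match -> dn blocked
  list(boxes = boxes, classes = classes, gt_index = gt_index,
       positive = positive, mask = mask, n_dn = n_dn, n_groups = n_groups)
}

.level_anchors <- function(level_hw) {
  anchors <- lapply(seq_along(level_hw), function(l) {
    h <- level_hw[[l]][1]; w <- level_hw[[l]][2]
    cy <- (rep(seq_len(h), times = w) - 0.5) / h
    cx <- (rep(seq_len(w), each = h) - 0.5) / w
    cbind(cx, cy, 0.05 * 2^(l - 1), 0.05 * 2^(l - 1))
  })
  do.call(rbind, anchors)
}

# multi-scale deformable cross-attention (per-query sampling of the value
# pyramid at offset points around the reference box)
ms_deform_attn_fwd <- function(ly, content, qpos, ref, memory, level_hw, heads,
                               points) {
  nq <- nrow(content); d <- ncol(content)
  M <- heads; dh <- d %/% M; L <- length(level_hw); P <- points
  off <- linear_fwd(ly$offsets, content + qpos)     # [nq, M*L*P*2]
  wts <- linear_fwd(ly$weights, content + qpos)     # [nq, M*L*P]
  # softmax over levels x points per head
  wts <- array(wts, c(nq, M, L * P))
  for (m in seq_len(M)) wts[, m, ] <- softmax_rows(matrix(wts[, m, ], nrow = nq))
  val <- linear_fwd(ly$value_proj, memory)          # [n_mem, d]
  # split memory rows by level
  sizes <- vapply(level_hw, prod, numeric(1))
  starts <- cumsum(c(0, sizes))
  out <- matrix(0, nq, d)
  off <- array(off, c(nq, M, L, P, 2))
  for (m in seq_len(M)) {
    cols <- (m - 1L) * dh + seq_len(dh)
    acc <- matrix(0, nq, dh)
    for (l in seq_len(L)) {
      h <- level_hw[[l]][1]; w <- level_hw[[l]][2]
      vmap <- array(val[starts[l] + seq_len(sizes[l]), cols, drop = FALSE],
                    c(h, w, dh))
      for (p in seq_len(P)) {
        sx <- ref[, 1] + off[, m, l, p, 1] / P * ref[, 3] * 0.5
        sy <- ref[, 2] + off[, m, l, p, 2] / P * ref[, 4] * 0.5
        pts <- cbind(2 * sx - 1, 2 * sy - 1)        # [0,1] -> [-1,1]
        samp <- bilinear_sample(vmap, pts)
        acc <- acc + samp * wts[, m, (l - 1L) * P + p]
      }
    }
    out[, cols] <- acc
  }
  linear_fwd(ly$out_proj, out)
}

#' Decode a fused pyramid into a detection set
#'
#' Selects top-K encoder tokens as initial queries (their predicted boxes
#' become the references), optionally prepends denoising queries with the
#' masking contract, and runs the iterative decoder. Each layer refines the
#' reference boxes through sigmoid-space deltas; with all-zero decoder
#' weights the references pass through unchanged.
#'
#' @param dec decoder built with `init = TRUE`.
#' @param pyramid list of `P3`, `P4`, `P5` fused maps.
#' @param image_size side length used to scale boxes to pixels.
#' @param dn optional denoising fragment from [denoising_queries()].
#' @param aux keep per-layer auxiliary outputs (training).
#' @return list with `detections` (data.frame x1, y1, x2, y2, cls, conf sorted
#'   by decreasing confidence, boxes clipped to the image), `layers` (per-layer
#'   logits and normalized cxcywh boxes for the matching queries), and `dn_layers`
#'   (same for denoising queries, when `dn` is supplied).
#' @export
decode <- function(dec, pyramid, image_size = 640, dn = NULL, aux = TRUE) {
  cfg <- dec$cfg
  levels <- list(pyramid$P3, pyramid$P4, pyramid$P5)
  level_hw <- lapply(levels, function(x) dim(x)[1:2])
  memory <- do.call(rbind, lapply(levels, flatten_hw))
  mem_n <- ln_fwd(dec$enc_ln, linear_fwd(dec$enc_output, memory))
  scores <- linear_fwd(dec$enc_score, mem_n)
  K <- cfg$n_queries
  sel <- select_queries(scores, K)
  anchors <- .level_anchors(level_hw)
  ref_logit <- mlp_fwd(dec$enc_bbox, mem_n[sel, , drop = FALSE]) +
    .inv_sigmoid(anchors[sel, , drop = FALSE])
  ref <- 1 / (1 + exp(-ref_logit))
  content <- mem_n[sel, , drop = FALSE]

  n_dn <- 0L
  mask <- NULL
  if (!is.null(dn)) {
    n_dn <- dn$n_dn
    content <- rbind(dec$dn_label_embed[dn$classes + 1L, , drop = FALSE], content)
    ref <- rbind(dn$boxes, ref)
    mask <- dn$mask
  }

  layers_out <- list()
  dn_out <- list()
  for (li in seq_along(dec$layers)) {
    ly <- dec$layers[[li]]
    qpos <- mlp_fwd(dec$query_pos, ref)
    sa <- mha_fwd(ly$self_attn, content + qpos, content + qpos, content,
                  mask = mask)
    content <- ln_fwd(ly$ln1, content + sa)
    ca <- ms_deform_attn_fwd(ly, content, qpos, ref, memory, level_hw,
                             cfg$heads, cfg$points)
    content <- ln_fwd(ly$ln2, content + ca)
    ff <- linear_fwd(ly$ffn2, act_fwd(linear_fwd(ly$ffn1, content), "relu"))
    content <- ln_fwd(ly$ln3, content + ff)
    delta <- mlp_fwd(ly$bbox_head, content)
    ref_in <- ref
    ref <- 1 / (1 + exp(-(.inv_sigmoid(ref) + delta)))
    logits <- linear_fwd(ly$cls_head, content)
    keep <- if (n_dn > 0L) (n_dn + 1L):nrow(ref) else seq_len(nrow(ref))
    if (aux || li == length(dec$layers)) {
      layers_out[[length(layers_out) + 1L]] <-
        list(logits = logits[keep, , drop = FALSE],
             boxes = ref[keep, , drop = FALSE],
             embed = content[keep, , drop = FALSE],
             ref_in = ref_in[keep, , drop = FALSE])
      if (n_dn > 0L) {
        dn_out[[length(dn_out) + 1L]] <-
          list(logits = logits[seq_len(n_dn), , drop = FALSE],
               boxes = ref[seq_len(n_dn), , drop = FALSE])
      }
    }
  }

  fin <- layers_out[[length(layers_out)]]
  p <- 1 / (1 + exp(-fin$logits))
  conf <- apply(p, 1, max)
  cls <- max.col(p, ties.method = "first") - 1L
  bx <- box_cxcywh_to_xyxy(fin$boxes * image_size)
  bx <- .as_box_matrix(bx)
  bx[, c(1, 3)] <- pmin(pmax(bx[, c(1, 3)], 0), image_size)
  bx[, c(2, 4)] <- pmin(pmax(bx[, c(2, 4)], 0), image_size)
  det <- data.frame(x1 = bx[, 1], y1 = bx[, 2], x2 = bx[, 3], y2 = bx[, 4],
                    cls = cls, conf = conf)
  det <- det[order(-det$conf), , drop = FALSE]
  rownames(det) <- NULL
  list(detections = det, layers = layers_out, dn_layers = dn_out)
}

# ---- set-prediction loss ----------------------------------------------------

.varifocal_terms <- function(p, target, alpha = 0.75, gamma = 2) {
  # p, target: same-shape matrices; target is the IoU-quality target
  # (0 for negatives). Returns the per-entry loss.
  pos <- target > 0
  loss <- matrix(0, nrow(p), ncol(p))
  eps <- 1e-9
  loss[pos] <- -(target[pos] * log(p[pos] + eps) +
                   (1 - target[pos]) * log(1 - p[pos] + eps))
  loss[!pos] <- -alpha * p[!pos]^gamma * log(1 - p[!pos] + eps)
  loss
}

.match_cost <- function(logits, boxes, t_boxes, t_classes, w = c(2, 5, 2)) {
  p <- 1 / (1 + exp(-logits))
  nq <- nrow(boxes); ng <- nrow(t_boxes)
  cost <- matrix(0, nq, ng)
  for (j in seq_len(ng)) {
    l1 <- rowSums(abs(boxes - matrix(t_boxes[j, ], nq, 4, byrow = TRUE)))
    gi <- giou(box_cxcywh_to_xyxy(boxes),
               box_cxcywh_to_xyxy(matrix(t_boxes[j, ], 1)), format = "xyxy")
    cost[, j] <- w[1] * (-p[, t_classes[j] + 1L]) + w[2] * l1 + w[3] * (1 - gi)
  }
  cost
}

.layer_loss <- function(logits, boxes, t_boxes, t_classes, loss_cfg,
                        pairs = NULL) {
  # pairs: fixed (query, gt) assignment (denoising); otherwise Hungarian
  nq <- nrow(boxes)
  S <- ncol(logits)
  bfn <- box_loss_fn(loss_cfg$box, loss_cfg$inner_ratio)
  if (nrow(t_boxes) == 0) {
    p <- 1 / (1 + exp(-logits))
    return(list(cls = sum(.varifocal_terms(p, matrix(0, nq, S))) / max(nq, 1),
                l1 = 0, box = 0))
  }
  if (is.null(pairs)) {
    cost <- .match_cost(logits, boxes, t_boxes, t_classes,
                        w = loss_cfg$match_weights)
    pairs <- hungarian_match(cost)$pairs
  }
  pred_m <- boxes[pairs[, 1], , drop = FALSE]
  gt_m <- t_boxes[pairs[, 2], , drop = FALSE]
  qual <- iou(box_cxcywh_to_xyxy(pred_m), box_cxcywh_to_xyxy(gt_m))
  target <- matrix(0, nq, S)
  target[cbind(pairs[, 1], t_classes[pairs[, 2]] + 1L)] <- pmax(qual, 1e-3)
  p <- 1 / (1 + exp(-logits))
  cls <- sum(.varifocal_terms(p, target)) / nrow(pairs)
  l1 <- sum(abs(pred_m - gt_m)) / nrow(pairs)
  box <- sum(bfn(box_cxcywh_to_xyxy(pred_m), box_cxcywh_to_xyxy(gt_m))) /
    nrow(pairs)
  list(cls = cls, l1 = l1, box = box)
}

#' Loss configuration
#'
#' @param box IoU-family box loss: `"giou"`, `"eiou"` or `"inner_eiou"`.
#' @param inner_ratio auxiliary-box ratio for Inner-EIoU.
#' @param weights loss weights (classification, L1, IoU-family).
#' @param match_weights Hungarian matching cost weights (same order).
#' @return list of class `loss_config`.
#' @export
loss_config <- function(box = c("giou", "eiou", "inner_eiou"),
                        inner_ratio = 0.7, weights = c(1, 5, 2),
                        match_weights = c(2, 5, 2)) {
  box <- match.arg(box)
  structure(list(box = box, inner_ratio = inner_ratio, weights = weights,
                 match_weights = match_weights), class = "loss_config")
}

#' Total training loss of a decoded output
#'
#' Weighted sum of classification (IoU-weighted focal), L1 and the configured
#' IoU-family box loss, summed over decoder layers and denoising groups.
#'
#' @param out output of [decode()] (with `aux = TRUE`).
#' @param target list with `boxes` (n_gt x 4 normalized cxcywh) and `classes`
#'   (0-based ids).
#' @param loss_cfg a [loss_config()].
#' @param dn the denoising fragment passed to [decode()], if any.
#' @return list with `loss` (scalar) and `components` (per-layer data.frame).
#' @export
total_loss <- function(out, target, loss_cfg = loss_config(), dn = NULL) {
  w <- loss_cfg$weights
  rows <- list()
  tot <- 0
  for (li in seq_along(out$layers)) {
    lo <- out$layers[[li]]
    comp <- .layer_loss(lo$logits, lo$boxes, target$boxes, target$classes,
                        loss_cfg)
    contrib <- w[1] * comp$cls + w[2] * comp$l1 + w[3] * comp$box
    tot <- tot + contrib
    rows[[length(rows) + 1L]] <- data.frame(part = "match", layer = li,
                                            cls = comp$cls, l1 = comp$l1,
                                            box = comp$box)
  }
  if (!is.null(dn) && length(out$dn_layers)) {
    pos <- which(dn$positive)
    pairs <- cbind(row = pos, col = dn$gt_index[pos])
    for (li in seq_along(out$dn_layers)) {
      lo <- out$dn_layers[[li]]
      comp <- .layer_loss(lo$logits, lo$boxes, target$boxes, target$classes,
                          loss_cfg, pairs = pairs)
      contrib <- w[1] * comp$cls + w[2] * comp$l1 + w[3] * comp$box
      tot <- tot + contrib
      rows[[length(rows) + 1L]] <- data.frame(part = "denoise", layer = li,
                                              cls = comp$cls, l1 = comp$l1,
                                              box = comp$box)
    }
  }
  list(loss = tot, components = do.call(rbind, rows))
}
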