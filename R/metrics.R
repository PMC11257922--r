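# Detection evaluation: greedy confidence-ordered matching, precision/recall,
# F1, per-class AP (101-point interpolation), mAP50, mAP50:95, confusion
# matrix, and a wall-clock FPS harness.

#' Greedy TP/FP matching of detections against ground truth
#'
#' Detections are processed in decreasing confidence; a detection is a true
#' positive iff it has the same class as, and IoU >= `iou_thr` with, a
#' not-yet-matched ground-truth box. Each ground truth is matched at most once;
#' duplicate detections of one object count as false positives.
#'
#' @param dets data.frame with columns x1, y1, x2, y2, cls, conf.
#' @param gts data.frame with columns x1, y1, x2, y2, cls.
#' @param iou_thr IoU threshold for a positive match.
#' @return `dets` ordered by decreasing confidence with logical column `tp`
#'   and integer column `gt_idx` (0 for false positives); attribute `n_gt`.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  dets <- dets[order(-dets$conf), , drop = FALSE]
  nd <- nrow(dets); ng <- nrow(gts)
  tp <- logical(nd); gt_idx <- integer(nd)
  taken <- logical(ng)
  if (nd > 0 && ng > 0) {
    iom <- iou_matrix(as.matrix(dets[, c("x1", "y1", "x2", "y2")]),
                      as.matrix(gts[, c("x1", "y1", "x2", "y2")]))
    for (i in seq_len(nd)) {
      cand <- which(!taken & gts$cls == dets$cls[i] & iom[i, ] >= iou_thr)
      if (length(cand)) {
        j <- cand[which.max(iom[i, cand])]
        tp[i] <- TRUE; gt_idx[i] <- j; taken[j] <- TRUE
      }
    }
  }
  dets$tp <- tp
  dets$gt_idx <- gt_idx
  attr(dets, "n_gt") <- ng
  dets
}

#' Average precision from a ranked TP/FP sequence
#'
#' Integrates precision over recall with 101-point interpolation (precision at
#' each recall level is the maximum precision at any recall >= that level).
#'
#' @param tp logical vector in decreasing-confidence order.
#' @param n_gt number of ground-truth instances for the class.
#' @return AP in \[0, 1\] (0 when there are no detections).
#' @export
average_precision <- function(tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  # interpolated precision: running max from the right
  p_interp <- rev(cummax(rev(precision)))
  rec_grid <- seq(0, 1, by = 0.01)
  p_at <- vapply(rec_grid, function(r) {
    k <- which(recall >= r)
    if (length(k)) p_interp[k[1]] else 0
  }, numeric(1))
  mean(p_at)
}

#' Full detection evaluation report
#'
#' Computes per-class AP at IoU 0.5, mAP50, mAP50:95 (IoU 0.50 to 0.95 in
#' steps of 0.05), macro precision/recall/F1 at the confidence threshold that
#' maximizes macro F1, and the confusion matrix at that threshold.
#'
#' @param dets list of per-image detection data.frames
#'   (columns x1, y1, x2, y2, cls, conf).
#' @param gts list of per-image ground-truth data.frames
#'   (columns x1, y1, x2, y2, cls).
#' @param classes character vector of class names; class ids are 0-based
#'   indices into this vector.
#' @return list with `ap50` (named per-class), `map50`, `map5095`, `precision`,
#'   `recall`, `f1`, `conf_threshold`, `confusion` (the (S+1) x (S+1) matrix).
#' @export
map_suite <- function(dets, gts, classes = ripeness_classes()$name) {
  stopifnot(length(dets) == length(gts))
  S <- length(classes)
  iou_grid <- seq(0.5, 0.95, by = 0.05)

  # flatten matches at each IoU threshold
  ap_at <- function(thr) {
    flat <- do.call(rbind, lapply(seq_along(dets), function(i) {
      m <- match_detections(dets[[i]], gts[[i]], iou_thr = thr)
      if (nrow(m)) cbind(m[, c("cls", "conf", "tp")], img = i) else NULL
    }))
    gt_counts <- tabulate(unlist(lapply(gts, function(g) g$cls)) + 1L, nbins = S)
    vapply(seq_len(S) - 1L, function(cl) {
      n_gt <- gt_counts[cl + 1L]
      if (n_gt == 0) {
        warning(sprintf("class '%s' has no ground truths; excluded from mAP",
                        classes[cl + 1L]))
        return(NA_real_)
      }
      if (is.null(flat)) return(0)
      sub <- flat[flat$cls == cl, , drop = FALSE]
      if (nrow(sub) == 0) return(0)
      sub <- sub[order(-sub$conf), , drop = FALSE]
      average_precision(sub$tp, n_gt)
    }, numeric(1))
  }

  ap50 <- ap_at(0.5)
  names(ap50) <- classes
  aps <- vapply(iou_grid, function(t) mean(ap_at(t), na.rm = TRUE), numeric(1))
  map50 <- mean(ap50, na.rm = TRUE)
  map5095 <- mean(aps)

  # macro P/R/F1 at the F1-maximizing confidence threshold
  confs <- sort(unique(unlist(lapply(dets, function(d) d$conf))), decreasing = TRUE)
  if (length(confs) == 0) confs <- 0.5
  prf <- function(thr) {
    tp <- fp <- fn <- numeric(S)
    for (i in seq_along(dets)) {
      d <- dets[[i]][dets[[i]]$conf >= thr, , drop = FALSE]
      m <- match_detections(d, gts[[i]], iou_thr = 0.5)
      for (cl in seq_len(S) - 1L) {
        tp[cl + 1L] <- tp[cl + 1L] + sum(m$tp & m$cls == cl)
        fp[cl + 1L] <- fp[cl + 1L] + sum(!m$tp & m$cls == cl)
        fn[cl + 1L] <- fn[cl + 1L] + sum(gts[[i]]$cls == cl) - sum(m$tp & m$cls == cl)
      }
    }
    p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    keep <- (tp + fn) > 0          # macro over classes present in ground truth
    P <- mean(p[keep]); R <- mean(r[keep])
    F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
    c(P = P, R = R, F1 = F1)
  }
  cand <- unique(stats::quantile(confs, probs = seq(0, 1, 0.1), names = FALSE, type = 1))
  scores <- vapply(cand, function(t) prf(t)["F1"], numeric(1))
  best <- cand[which.max(scores)]
  at_best <- prf(best)

  list(ap50 = ap50,
       map50 = map50,
       map5095 = map5095,
       precision = unname(at_best["P"]),
       recall = unname(at_best["R"]),
       f1 = unname(at_best["F1"]),
       conf_threshold = best,
       confusion = confusion_matrix(dets, gts, iou_thr = 0.5,
                                    conf_thr = best, classes = classes))
}

#' Detection confusion matrix
#'
#' Rows are predicted classes plus background; columns are true classes plus
#' background. Unmatched detections land in (predicted class, background);
#' missed ground truths in (background, true class). Matching ignores class so
#' that ripeness confusions between overlapping boxes are visible off-diagonal.
#'
#' @inheritParams map_suite
#' @param iou_thr IoU threshold for localization.
#' @param conf_thr detections below this confidence are dropped.
#' @return (S+1) x (S+1) integer matrix with dimnames.
#' @export
confusion_matrix <- function(dets, gts, iou_thr = 0.5, conf_thr = 0.25,
                             classes = ripeness_classes()$name) {
  S <- length(classes)
  lab <- c(classes, "background")
  cm <- matrix(0L, S + 1, S + 1, dimnames = list(predicted = lab, true = lab))
  for (i in seq_along(dets)) {
    d <- dets[[i]][dets[[i]]$conf >= conf_thr, , drop = FALSE]
    d <- d[order(-d$conf), , drop = FALSE]
    g <- gts[[i]]
    taken <- logical(nrow(g))
    matched_det <- logical(nrow(d))
    if (nrow(d) && nrow(g)) {
      iom <- iou_matrix(as.matrix(d[, c("x1", "y1", "x2", "y2")]),
                        as.matrix(g[, c("x1", "y1", "x2", "y2")]))
      for (k in seq_len(nrow(d))) {
        cand <- which(!taken & iom[k, ] >= iou_thr)
        if (length(cand)) {
          j <- cand[which.max(iom[k, cand])]
          taken[j] <- TRUE; matched_det[k] <- TRUE
          cm[d$cls[k] + 1L, g$cls[j] + 1L] <- cm[d$cls[k] + 1L, g$cls[j] + 1L] + 1L
        }
      }
    }
    if (nrow(d)) for (k in which(!matched_det)) {
      cm[d$cls[k] + 1L, S + 1L] <- cm[d$cls[k] + 1L, S + 1L] + 1L
    }
    if (nrow(g)) for (j in which(!taken)) {
      cm[S + 1L, g$cls[j] + 1L] <- cm[S + 1L, g$cls[j] + 1L] + 1L
    }
  }
  cm
}

#' Wall-clock inference timing
#'
#' Mean seconds per image after warm-up, and FPS = 1 / t_avg. Hardware
#' dependent; reported for information only.
#'
#' @param model a built model (see [build_model()]).
#' @param images list of image arrays (H x W x 3).
#' @param warmup number of initial repetitions discarded.
#' @param reps number of timed repetitions over the image list.
#' @return list with `t_avg` (seconds/image) and `fps`.
#' @export
time_inference <- function(model, images, warmup = 1, reps = 3) {
  stopifnot(reps >= 1)
  for (k in seq_len(warmup)) for (im in images) model_forward(model, im)
  t0 <- proc.time()[["elapsed"]]
  for (k in seq_len(reps)) for (im in images) model_forward(model, im)
  t1 <- proc.time()[["elapsed"]]
  t_avg <- (t1 - t0) / (reps * length(images))
  list(t_avg = t_avg, fps = 1 / t_avg)
}
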