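mk_det <- function(x1, y1, x2, y2, cls, conf) {
  data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2, cls = cls, conf = conf)
}
mk_gt <- function(x1, y1, x2, y2, cls) {
  data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2, cls = cls)
}

test_that("greedy matching: perfect, duplicate and random cases", {
  gt <- mk_gt(c(0, 50), c(0, 50), c(10, 70), c(10, 70), c(0, 1))
  perfect <- mk_det(c(0, 50), c(0, 50), c(10, 70), c(10, 70), c(0, 1), c(0.9, 0.8))
  m <- match_detections(perfect, gt)
  expect_true(all(m$tp))
  # duplicate detections of one object: one TP, one FP
  dup <- mk_det(c(0, 0.5), c(0, 0), c(10, 10.5), c(10, 10), c(0, 0), c(0.9, 0.8))
  m2 <- match_detections(dup, gt[1, ])
  expect_equal(sum(m2$tp), 1)
  expect_equal(sum(!m2$tp), 1)
  # random instances agree with an independent implementation of the rule
  set.seed(31)
  for (rep in 1:30) {
    ng <- sample(1:5, 1); nd <- sample(1:7, 1)
    g <- do.call(rbind, lapply(seq_len(ng), function(i) {
      b <- rand_box(20); mk_gt(b[1], b[2], b[3], b[4], sample(0:2, 1))
    }))
    d <- do.call(rbind, lapply(seq_len(nd), function(i) {
      b <- rand_box(20)
      mk_det(b[1], b[2], b[3], b[4], sample(0:2, 1), runif(1))
    }))
    m <- match_detections(d, g, iou_thr = 0.3)
    expect_equal(sum(m$tp), greedy_tp_count(d, g, 0.3))
  }
})

test_that("average precision matches the hand-enumerated staircase", {
  # 3 detections, 2 ground truths: TP, FP, TP in confidence order
  tp <- c(TRUE, FALSE, TRUE)
  expect_equal(average_precision(tp, 2), staircase_ap(tp, 2))
  # closed-form check of that staircase: p@r grid = 1 for r <= 0.5 (prec 1
  # at recall 0.5), 2/3 for r in (0.5, 1]
  expect_equal(average_precision(tp, 2), (51 * 1 + 50 * (2 / 3)) / 101)
  expect_equal(average_precision(logical(0), 2), 0)
  expect_equal(average_precision(c(TRUE, TRUE), 2), 1)
})

test_that("removing a false positive never decreases AP", {
  set.seed(8)
  for (rep in 1:50) {
    n <- sample(3:10, 1)
    tp <- runif(n) > 0.5
    if (!any(!tp)) tp[sample(n, 1)] <- FALSE
    n_gt <- max(1, sum(tp))
    fp_pos <- which(!tp)
    drop_idx <- fp_pos[sample.int(length(fp_pos), 1)]
    expect_gte(average_precision(tp[-drop_idx], n_gt) + 1e-12,
               average_precision(tp, n_gt))
  }
})

test_that("map_suite yields sane aggregate metrics and mAP50 >= mAP50:95", {
  set.seed(12)
  gts <- lapply(1:4, function(i) {
    do.call(rbind, lapply(1:3, function(j) {
      b <- rand_box(100); mk_gt(b[1], b[2], b[3], b[4], sample(0:4, 1))
    }))
  })
  dets <- lapply(gts, function(g) {
    jit <- g
    jit$x1 <- jit$x1 + runif(3, -1, 1); jit$x2 <- jit$x2 + runif(3, -1, 1)
    mk_det(jit$x1, jit$y1, jit$x2, jit$y2, jit$cls, runif(3, 0.5, 1))
  })
  suppressWarnings(ev <- map_suite(dets, gts))
  expect_true(all(is.finite(c(ev$map50, ev$map5095, ev$precision, ev$recall,
                              ev$f1))))
  expect_gte(ev$map50, ev$map5095)
  expect_true(all(ev$ap50 >= 0 & ev$ap50 <= 1, na.rm = TRUE))
  expect_equal(ev$f1, 2 * ev$precision * ev$recall /
                 (ev$precision + ev$recall))
})

test_that("confusion matrix bookkeeping", {
  gt <- mk_gt(c(0, 50), c(0, 50), c(10, 70), c(10, 70), c(0, 1))
  perfect <- mk_det(c(0, 50), c(0, 50), c(10, 70), c(10, 70), c(0, 1), c(0.9, 0.8))
  cm <- confusion_matrix(list(perfect), list(gt), conf_thr = 0.5)
  expect_equal(sum(diag(cm)), 2)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  # class-swapped predictions: zero diagonal for the swapped pair
  sw <- perfect; sw$cls <- c(1, 0)
  cm2 <- confusion_matrix(list(sw), list(gt), conf_thr = 0.5)
  expect_equal(diag(cm2)[1:2], c(unripe = 0, half_ripe = 0))
  expect_equal(cm2[2, 1], 1)   # predicted half_ripe, true unripe
  # column sums over object classes equal ground-truth class counts
  set.seed(4)
  gts <- lapply(1:3, function(i) {
    do.call(rbind, lapply(1:4, function(j) {
      b <- rand_box(100); mk_gt(b[1], b[2], b[3], b[4], sample(0:4, 1))
    }))
  })
  dets <- lapply(gts, function(g)
    mk_det(g$x1, g$y1, g$x2, g$y2, sample(0:4, nrow(g), replace = TRUE),
           runif(nrow(g), 0.6, 1)))
  cm3 <- confusion_matrix(dets, gts, conf_thr = 0.5)
  gt_counts <- tabulate(unlist(lapply(gts, function(g) g$cls)) + 1L, nbins = 5)
  expect_equal(unname(colSums(cm3)[1:5]), gt_counts)
})

test_that("timing harness satisfies its definitional contract", {
  m <- build_model(model_config(preset = "smoke"), init = TRUE, seed = 2)
  img <- generate_scene(scene_spec(image_size = 320, n_fruits = 1, seed = 3))$image
  tr <- time_inference(m, list(img), warmup = 0, reps = 1)
  expect_equal(tr$fps * tr$t_avg, 1)
  expect_gt(tr$t_avg, 0)
})
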