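test_that("IoU and GIoU match hand arithmetic and limiting cases", {
  a <- c(0, 0, 4, 4); b <- c(2, 2, 6, 6)
  expect_equal(iou(a, b), 4 / 28)
  expect_equal(iou(a, a), 1)
  expect_equal(giou(a, a), 1)
  # far-separated unit boxes: IoU 0, GIoU approaching -1
  far <- giou(c(0, 0, 1, 1), c(999, 999, 1000, 1000))
  expect_equal(iou(c(0, 0, 1, 1), c(999, 999, 1000, 1000)), 0)
  expect_lt(far, -0.99)
  # degenerate box warns but returns a clamped value
  expect_warning(v <- iou(c(0, 0, 0, 1), c(0, 0, 2, 2)), "degenerate")
  expect_true(is.finite(v))
})

test_that("IoU and inner-IoU agree with a rasterization oracle on 1000 random pairs", {
  set.seed(42)
  for (i in 1:1000) {
    a <- rand_box(); b <- rand_box()
    expect_lt(abs(iou(a, b) - raster_iou(a, b)), 1e-3)
  }
  set.seed(43)
  for (i in 1:200) {
    a <- rand_box(); b <- rand_box()
    r <- runif(1, 0.5, 1.5)
    expect_lt(abs(inner_iou(a, b, ratio = r) - raster_inner_iou(a, b, r)), 1e-3)
  }
  # a worked pair at the default ratio
  a <- c(0, 0, 4, 4); b <- c(2, 2, 6, 6)
  expect_lt(abs(inner_iou(a, b, ratio = 0.7) - raster_inner_iou(a, b, 0.7)),
            1e-3)
})

test_that("inner-IoU reduces to IoU at ratio 1 and is continuous in the ratio", {
  set.seed(7)
  for (i in 1:50) {
    a <- rand_box(); b <- rand_box()
    expect_equal(inner_iou(a, b, ratio = 1), iou(a, b))
  }
  a <- c(0, 0, 4, 4); b <- c(1, 1, 5, 6)
  rs <- seq(0.5, 1.5, by = 0.001)
  vals <- vapply(rs, function(r) inner_iou(a, b, ratio = r), numeric(1))
  expect_lt(max(abs(diff(vals))), 0.01)   # no jumps on a fine ratio grid
  expect_equal(inner_iou(a, a, ratio = 0.63), 1)
})

test_that("EIoU components behave as the decomposition demands", {
  a <- c(0, 0, 4, 4)
  e <- eiou(a, a)
  expect_equal(e$l_iou, 0); expect_equal(e$l_dis, 0); expect_equal(e$l_asp, 0)
  # same-shape boxes offset horizontally: aspect term zero, distance positive
  e2 <- eiou(a, c(1, 0, 5, 4))
  expect_equal(e2$l_asp, 0)
  expect_gt(e2$l_dis, 0)
  expect_equal(e2$loss, e2$l_iou + e2$l_dis + e2$l_asp)
})

test_that("all box losses vanish iff the boxes coincide and are translation invariant", {
  set.seed(11)
  for (i in 1:50) {
    a <- rand_box()
    expect_equal(eiou(a, a)$loss, 0)
    expect_equal(inner_eiou(a, a, ratio = 0.7), 0)
    expect_equal(1 - giou(a, a), 0)
    b <- rand_box()
    if (max(abs(a - b)) > 1e-6) {
      expect_gt(eiou(a, b)$loss, 0)
      expect_gt(inner_eiou(a, b, ratio = 0.7), 0)
    }
    sh <- runif(2, -5, 5)
    a2 <- a + sh[c(1, 2, 1, 2)]; b2 <- b + sh[c(1, 2, 1, 2)]
    expect_equal(eiou(a2, b2)$loss, eiou(a, b)$loss)
    expect_equal(inner_eiou(a2, b2, 0.7), inner_eiou(a, b, 0.7))
    expect_equal(giou(a2, b2), giou(a, b))
  }
})

test_that("Inner-EIoU equals EIoU exactly at ratio 1 and assembles from its parts", {
  set.seed(5)
  for (i in 1:50) {
    a <- rand_box(); b <- rand_box()
    expect_equal(inner_eiou(a, b, ratio = 1), eiou(a, b)$loss)
    expect_equal(inner_eiou(a, b, ratio = 0.7),
                 eiou(a, b)$loss + iou(a, b) - inner_iou(a, b, 0.7))
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(99)
  num_grad <- function(fn, p, eps = 1e-6) {
    vapply(1:4, function(k) {
      pp <- p; pm <- p
      pp[k] <- pp[k] + eps; pm[k] <- pm[k] - eps
      (fn(pp) - fn(pm)) / (2 * eps)
    }, numeric(1))
  }
  for (i in 1:30) {
    p <- c(runif(2, 2, 8), runif(2, 1, 4))   # cxcywh
    g <- c(runif(2, 2, 8), runif(2, 1, 4))
    ag <- eiou_grad(p, g)
    ng <- num_grad(function(q) eiou(box_cxcywh_to_xyxy(q),
                                    box_cxcywh_to_xyxy(g))$loss, p)
    expect_equal(ag$grad, ng, tolerance = 1e-4)
    ag2 <- inner_eiou_grad(p, g, ratio = 0.7)
    ng2 <- num_grad(function(q) inner_eiou(box_cxcywh_to_xyxy(q),
                                           box_cxcywh_to_xyxy(g), 0.7), p)
    expect_equal(ag2$grad, ng2, tolerance = 1e-4)
    ag3 <- giou_grad(p, g)
    ng3 <- num_grad(function(q) 1 - giou(box_cxcywh_to_xyxy(q),
                                         box_cxcywh_to_xyxy(g)), p)
    expect_equal(ag3$grad, ng3, tolerance = 1e-4)
  }
})
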