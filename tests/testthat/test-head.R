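test_that("query selection is a stable top-K by maximum class score", {
  set.seed(1)
  logits <- matrix(rnorm(20 * 5), 20, 5)
  logits[7, 3] <- 10                      # one dominant token
  expect_equal(select_queries(logits, 1), 7L)
  # agreement with an explicit sort oracle
  K <- 6
  sel <- select_queries(logits, K)
  oracle <- order(-apply(logits, 1, max))[1:K]
  expect_equal(sort(sel), sort(oracle))
  # stable tie-break by index
  tied <- matrix(0, 10, 2)
  expect_equal(select_queries(tied, 3), 1:3)
  expect_error(select_queries(logits, 25), "exceeds")
})

test_that("denoising queries honour the noise bound and masking contract", {
  gt <- rbind(c(0.5, 0.5, 0.2, 0.2), c(0.3, 0.7, 0.1, 0.3))
  set.seed(2)
  dn0 <- denoising_queries(gt, c(0L, 3L), n_groups = 2, noise_scale = 0,
                           n_match = 5)
  pos <- dn0$positive
  expect_equal(dn0$boxes[pos, ], gt[dn0$gt_index[pos], ])   # zero noise
  expect_true(all(dn0$classes[pos] == c(0L, 3L)[dn0$gt_index[pos]]))
  expect_true(all(dn0$classes[!pos] != c(0L, 3L)[dn0$gt_index[!pos]]))
  # group count scales the fragment linearly
  set.seed(3)
  dn3 <- denoising_queries(gt, c(0L, 3L), n_groups = 3, noise_scale = 0.2,
                           n_match = 5)
  expect_equal(dn3$n_dn, 3 * 2 * 2)
  expect_equal(dn0$n_dn, 2 * 2 * 2)
  # mask: denoise -> match and match -> denoise fully blocked
  n_dn <- dn3$n_dn
  expect_true(all(dn3$mask[seq_len(n_dn), n_dn + 1:5]))
  expect_true(all(dn3$mask[n_dn + 1:5, seq_len(n_dn)]))
  # cross-group blocked, own group open
  g1 <- 1:4; g2 <- 5:8; g3 <- 9:12
  expect_true(all(dn3$mask[g1, g2]))
  expect_true(all(dn3$mask[g2, g3]))
  expect_false(any(dn3$mask[g1, g1]))
})

mk_smoke_fused <- function(seed = 4, hw = 8L, d = 16L) {
  set.seed(seed)
  list(P3 = array(rnorm(hw * hw * d), c(hw, hw, d)),
       P4 = array(rnorm(hw / 2 * hw / 2 * d), c(hw / 2, hw / 2, d)),
       P5 = array(rnorm(hw / 4 * hw / 4 * d), c(hw / 4, hw / 4, d)))
}

mk_dec <- function(seed = 4, nq = 10L, layers = 2L, d = 16L, hw = 8L) {
  set.seed(seed)
  build_decoder(head_config(n_queries = nq, dec_layers = layers, d_model = d,
                            heads = 2L, points = 2L, ffn_dim = 32L),
                num_classes = 5L,
                level_hw = list(c(hw, hw), c(hw / 2, hw / 2), c(hw / 4, hw / 4)),
                init = TRUE)
}

test_that("zero box-head weights leave references unchanged through the decoder", {
  dec <- mk_dec()
  for (li in seq_along(dec$layers)) {
    for (k in 1:3) {
      dec$layers[[li]]$bbox_head[[k]]$w[] <- 0
      dec$layers[[li]]$bbox_head[[k]]$b[] <- 0
    }
  }
  fused <- mk_smoke_fused()
  out <- decode(dec, fused, image_size = 64, aux = TRUE)
  expect_equal(out$layers[[1]]$boxes, out$layers[[2]]$boxes, tolerance = 1e-9)
  expect_equal(out$layers[[1]]$ref_in, out$layers[[1]]$boxes, tolerance = 1e-9)
})

test_that("decode emits n_queries scored detections, sorted and clipped, deterministically", {
  dec <- mk_dec()
  fused <- mk_smoke_fused()
  out1 <- decode(dec, fused, image_size = 64)
  out2 <- decode(dec, fused, image_size = 64)
  expect_identical(out1$detections, out2$detections)
  d <- out1$detections
  expect_equal(nrow(d), 10)
  expect_true(all(diff(d$conf) <= 0))
  expect_true(all(d$x1 >= 0 & d$x2 <= 64 & d$y1 >= 0 & d$y2 <= 64))
  expect_true(all(d$conf >= 0 & d$conf <= 1))
  expect_true(all(d$cls %in% 0:4))
})

test_that("denoising queries flow through decode without touching matching outputs' shape", {
  dec <- mk_dec()
  fused <- mk_smoke_fused()
  gt <- rbind(c(0.5, 0.5, 0.2, 0.2))
  set.seed(5)
  dn <- denoising_queries(gt, 0L, n_groups = 2, noise_scale = 0.2, n_match = 10)
  out <- decode(dec, fused, image_size = 64, dn = dn, aux = TRUE)
  expect_equal(nrow(out$layers[[1]]$boxes), 10)
  expect_equal(nrow(out$dn_layers[[1]]$boxes), dn$n_dn)
})

test_that("total loss: zero at perfect predictions, isolated IoU-term swap, finite gradients", {
  target <- list(boxes = rbind(c(0.4, 0.4, 0.2, 0.2), c(0.7, 0.6, 0.1, 0.2)),
                 classes = c(1L, 3L))
  # build an output whose boxes equal the targets and whose logits are
  # confident in the right classes
  logits <- matrix(-8, 4, 5)
  logits[1, 2] <- 8; logits[2, 4] <- 8
  boxes <- rbind(target$boxes, c(0.1, 0.1, 0.05, 0.05), c(0.9, 0.9, 0.05, 0.05))
  out <- list(layers = list(list(logits = logits, boxes = boxes)))
  res <- total_loss(out, target, loss_config("giou"))
  expect_equal(res$components$l1, 0, tolerance = 1e-9)
  expect_equal(res$components$box, 0, tolerance = 1e-9)
  # swapping the IoU family changes only the box term
  set.seed(6)
  boxes2 <- boxes + runif(16, -0.03, 0.03)
  out2 <- list(layers = list(list(logits = logits, boxes = boxes2)))
  r_giou <- total_loss(out2, target, loss_config("giou"))
  r_inner <- total_loss(out2, target, loss_config("inner_eiou"))
  expect_equal(r_giou$components$cls, r_inner$components$cls)
  expect_equal(r_giou$components$l1, r_inner$components$l1)
  expect_false(isTRUE(all.equal(r_giou$components$box, r_inner$components$box)))
  # gradients of the training loss are finite on a random batch
  set.seed(7)
  lg <- ripedetr:::matching_loss_grad(matrix(rnorm(20), 4, 5),
                                      matrix(runif(16, 0.2, 0.8), 4, 4),
                                      target$boxes, target$classes,
                                      loss_config("inner_eiou"))
  expect_true(all(is.finite(lg$g_logits)))
  expect_true(all(is.finite(lg$g_boxes)))
  expect_true(is.finite(lg$loss))
})

test_that("empty ground truth sends every query to background", {
  logits <- matrix(rnorm(20), 4, 5)
  out <- list(layers = list(list(logits = logits,
                                 boxes = matrix(0.5, 4, 4))))
  res <- total_loss(out, list(boxes = matrix(numeric(0), 0, 4),
                              classes = integer(0)),
                    loss_config("giou"))
  expect_true(is.finite(res$loss))
  expect_equal(res$components$l1, 0)
  expect_equal(res$components$box, 0)
})
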