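test_that("channel shuffle is a fixed, invertible interleaving", {
  perm <- channel_shuffle_perm(8)
  expect_equal(perm, c(1, 5, 2, 6, 3, 7, 4, 8))
  inv <- order(perm)
  expect_equal(perm[inv], 1:8)
  set.seed(1)
  x <- array(rnorm(3 * 3 * 8), c(3, 3, 8))
  y <- ripedetr:::channel_shuffle(x)
  expect_identical(y[, , inv], x)                    # invertible
  # multiset of channel slices preserved
  sums_x <- sort(apply(x, 3, sum)); sums_y <- sort(apply(y, 3, sum))
  expect_equal(sums_y, sums_x)
  expect_error(channel_shuffle_perm(7))
})

test_that("GSConv interleaves its dense and depthwise halves and is lighter than a dense conv", {
  set.seed(2)
  prof <- ripedetr:::new_profile()
  gs <- ripedetr:::bld_gsconv(prof, "gs", 6L, 4L, 3, 1, c(5, 5), init = TRUE)
  x <- array(rnorm(5 * 5 * 6), c(5, 5, 6))
  y <- ripedetr:::gsconv_fwd(gs, x)
  a <- ripedetr:::convbn_fwd(gs$cv1, x)        # dense half
  b <- ripedetr:::convbn_fwd(gs$cv2, a)        # depthwise half
  expect_equal(dim(y), c(5, 5, 4))
  expect_equal(y[, , 1], a[, , 1]); expect_equal(y[, , 2], b[, , 1])
  expect_equal(y[, , 3], a[, , 2]); expect_equal(y[, , 4], b[, , 2])
  expect_error(ripedetr:::bld_gsconv(prof, "bad", 6L, 5L, 3, 1, c(5, 5), FALSE),
               "even")
  # parameter comparison for c_in = c_out = 16, k = 3
  prof2 <- ripedetr:::new_profile()
  ripedetr:::bld_gsconv(prof2, "gs", 16L, 16L, 3, 1, c(8, 8), init = FALSE)
  gs_params <- sum(ripedetr:::prof_table(prof2)$params)
  dense_params <- ripedetr:::conv_params(16, 16, 3) + 2 * 16   # conv + bn
  expect_lt(gs_params, dense_params)
})

test_that("GSbottleneck and VoVGSCSP: zero weights give zero output, stride 1 preserved", {
  set.seed(3)
  prof <- ripedetr:::new_profile()
  vov <- ripedetr:::bld_vovgscsp(prof, "vov", 8L, 4L, 1L, 0.5, c(6, 6),
                                 init = TRUE)
  x <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  y <- ripedetr:::vovgscsp_fwd(vov, x)
  expect_equal(dim(y), c(6, 6, 4))
  zero_all <- function(o) {   # zero weight fields only, keep structure
    if (!is.list(o)) return(o)
    for (nm in names(o)) {
      if (nm %in% c("w", "b", "gamma", "beta")) {
        o[[nm]] <- if (is.list(o[[nm]])) {
          lapply(o[[nm]], function(m) { m[] <- 0; m })
        } else { o[[nm]][] <- 0; o[[nm]] }
      } else if (is.list(o[[nm]])) {
        o[[nm]] <- zero_all(o[[nm]])
      }
    }
    o
  }
  vov0 <- zero_all(vov)
  y0 <- ripedetr:::vovgscsp_fwd(vov0, x)
  expect_true(all(y0 == 0))
  gsb <- ripedetr:::bld_gsbottleneck(prof, "gsb", 4L, c(6, 6), init = TRUE)
  yb <- ripedetr:::gsbottleneck_fwd(gsb, array(rnorm(6 * 6 * 4), c(6, 6, 4)))
  expect_equal(dim(yb), c(6, 6, 4))
})

test_that("SSFF: shape contract, constant-field behaviour, and the naive oracle", {
  set.seed(4)
  prof <- ripedetr:::new_profile()
  ss <- ripedetr:::bld_ssff(prof, "ssff", 8L, 3L, c(8, 8), init = TRUE)
  P3 <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  P4 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  P5 <- array(rnorm(2 * 2 * 8), c(2, 2, 8))
  y <- ripedetr:::ssff_fwd(ss, P3, P4, P5)
  expect_equal(dim(y), c(8, 8, 8))     # collapsed back to stride-8 resolution
  # constant inputs: spatially constant output
  yc <- ripedetr:::ssff_fwd(ss, array(0.3, dim(P3)), array(0.5, dim(P4)),
                            array(0.7, dim(P5)))
  expect_equal(max(apply(yc, 3, function(m) diff(range(m)))), 0)
  # naive oracle: project each level, nearest-upsample by explicit loops,
  # 3D-convolve the scale stack pointwise
  proj <- lapply(1:3, function(l) ripedetr:::convbn_fwd(ss$proj[[l]],
                                                        list(P3, P4, P5)[[l]]))
  up <- function(z, f) {
    d <- dim(z); out <- array(0, c(d[1] * f, d[2] * f, d[3]))
    for (i in seq_len(d[1] * f)) for (j in seq_len(d[2] * f)) {
      out[i, j, ] <- z[ceiling(i / f), ceiling(j / f), ]
    }
    out
  }
  stack <- list(proj[[1]], up(proj[[2]], 2), up(proj[[3]], 4))
  cm <- ss$cm
  naive <- array(0, c(8, 8, cm))
  for (i in 1:8) for (j in 1:8) {
    acc <- ss$b
    for (s in 1:3) acc <- acc + as.numeric(stack[[s]][i, j, ] %*% ss$w[, s, ])
    naive[i, j, ] <- acc
  }
  naive <- ripedetr:::act_fwd(ripedetr:::bn_fwd(ss$bn, naive), "silu")
  naive <- ripedetr:::convbn_fwd(ss$expand, naive)
  expect_equal(y, naive, tolerance = 1e-10)
  # channel mismatch is a config error
  expect_error(ripedetr:::ssff_fwd(ss, P3, P4[, , 1:4, drop = FALSE], P5),
               "mismatch")
})

test_that("every neck mode emits three maps with identical shapes", {
  set.seed(5)
  S <- list(S3 = array(rnorm(8 * 8 * 8), c(8, 8, 8)),
            S4 = array(rnorm(4 * 4 * 8), c(4, 4, 8)),
            S5 = array(rnorm(2 * 2 * 8), c(2, 2, 8)))
  shapes <- lapply(c("ccfm", "slimneck", "ssff", "slimneck_ssff"), function(md) {
    nk <- build_neck(neck_config(mode = md, fused_width = 8L, repc3_depth = 1L),
                     hw3 = c(8L, 8L), init = TRUE)
    out <- neck_forward(nk, S)
    lapply(out, dim)
  })
  for (i in 2:4) expect_identical(shapes[[i]], shapes[[1]])
  expect_identical(shapes[[1]]$P3, c(8L, 8L, 8L))
  expect_identical(shapes[[1]]$P5, c(2L, 2L, 8L))
})

test_that("neck modes order the parameter count as ssff > ccfm > slimneck_ssff > slimneck", {
  p_of <- function(md) profile_model(model_config(
    neck = neck_config(mode = md)))$total_params
  p <- vapply(c("ssff", "ccfm", "slimneck_ssff", "slimneck"), p_of, numeric(1))
  expect_true(p[["ssff"]] > p[["ccfm"]])
  expect_true(p[["ccfm"]] > p[["slimneck_ssff"]])
  expect_true(p[["slimneck_ssff"]] > p[["slimneck"]])
})
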