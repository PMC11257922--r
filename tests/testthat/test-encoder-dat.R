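test_that("reference grid covers the map uniformly, content-independent", {
  g <- reference_grid(2, 2, 1)
  expect_equal(nrow(g), 4)
  expect_equal(sort(unique(g[, "x"])), c(-1, 1))   # cell centers, [-1, 1]
  expect_equal(colMeans(g), c(x = 0, y = 0))       # symmetric about center
  g2 <- reference_grid(4, 4, 2)
  expect_equal(nrow(g2), 4)                        # factor 2 on 4x4 -> 2x2
  g3 <- reference_grid(5, 5, 1)
  expect_equal(diff(sort(unique(g3[, "x"]))), rep(0.5, 4))  # uniform spacing
})

test_that("bilinear sampling is exact interpolation", {
  set.seed(3)
  z <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  # integer grid locations return stored values
  g <- reference_grid(4, 4, 1)
  s <- bilinear_sample(z, g)
  expect_equal(s, matrix(z, 16, 3), tolerance = 1e-12)
  # midway between two horizontally adjacent cells: their mean
  p_mid <- cbind((g[1, 1] + g[5, 1]) / 2, g[1, 2])   # between (1,1) and (1,2)
  expect_equal(as.numeric(bilinear_sample(z, p_mid)),
               as.numeric((z[1, 1, ] + z[1, 2, ]) / 2))
  # out-of-range points clamp to the border
  expect_equal(as.numeric(bilinear_sample(z, cbind(-5, -5))),
               as.numeric(z[1, 1, ]))
  # random points against the naive kernel-sum definition
  kernel_sum <- function(pt) {
    px <- (pt[1] + 1) / 2 * 3 + 1; py <- (pt[2] + 1) / 2 * 3 + 1
    acc <- numeric(3)
    for (rx in 1:4) for (ry in 1:4) {
      acc <- acc + max(0, 1 - abs(px - rx)) * max(0, 1 - abs(py - ry)) * z[ry, rx, ]
    }
    acc
  }
  for (i in 1:20) {
    pt <- runif(2, -1, 1)
    expect_equal(as.numeric(bilinear_sample(z, rbind(pt))), kernel_sum(pt),
                 tolerance = 1e-12)
  }
})

mk_enc <- function(mode, hw = c(4, 4), d = 8, heads = 2, seed = 10) {
  set.seed(seed)
  ripedetr:::build_aifi(encoder_config(mode = mode, d_model = d, heads = heads,
                                       ffn_dim = 16),
                        hw = hw, init = TRUE)
}

test_that("zero offsets and zero bias reduce deformable attention to standard attention", {
  enc <- mk_enc("dat")
  enc$off_dw$w[[1]][] <- 0; enc$off_dw$b[] <- 0
  enc$off_proj$w[[1]][] <- 0; enc$off_proj$b[] <- 0
  enc$bias_table[] <- 0
  set.seed(4)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  got <- ripedetr:::dat_attention(enc, x)
  tok <- ripedetr:::flatten_hw(x)
  want <- ripedetr:::mhsa_tokens(enc, tok, tok)   # keys = grid samples = tokens
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("a single token makes attention the identity on the value path", {
  enc <- mk_enc("dat", hw = c(1, 1))
  set.seed(5)
  x <- array(rnorm(1 * 1 * 8), c(1, 1, 8))
  got <- ripedetr:::dat_attention(enc, x)
  tok <- matrix(x, 1, 8)
  v <- tok %*% enc$wv$w + matrix(enc$wv$b, 1, 8, byrow = TRUE)
  want <- v %*% enc$wo$w + matrix(enc$wo$b, 1, 8, byrow = TRUE)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("deformable attention matches the literal loop oracle on a 4x4 map", {
  enc <- mk_enc("dat", heads = 2)
  set.seed(6)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  expect_equal(ripedetr:::dat_attention(enc, x), naive_dat(enc, x),
               tolerance = 1e-8)
})

test_that("encoder layer preserves S5 shape in both modes; reshape inverts flatten", {
  set.seed(8)
  S5 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  for (mode in c("mhsa", "dat")) {
    enc <- mk_enc(mode)
    F5 <- aifi_forward(enc, S5)
    expect_equal(dim(F5), dim(S5))
    expect_true(all(is.finite(F5)))
  }
  expect_identical(ripedetr:::unflatten_hw(ripedetr:::flatten_hw(S5), 4, 4), S5)
})

test_that("token mixing is permutation-equivariant (positions permuted consistently)", {
  enc <- mk_enc("mhsa")
  set.seed(9)
  tok <- matrix(rnorm(16 * 8), 16, 8)
  perm <- sample(16)
  y <- ripedetr:::mhsa_tokens(enc, tok, tok)
  y_p <- ripedetr:::mhsa_tokens(enc, tok[perm, ], tok[perm, ])
  expect_equal(y_p, y[perm, ], tolerance = 1e-12)
})

test_that("attention rows sum to one after softmax", {
  set.seed(10)
  m <- ripedetr:::softmax_rows(matrix(rnorm(40), 5, 8))
  expect_equal(rowSums(m), rep(1, 5))
  expect_true(all(m > 0))
})

test_that("non-finite offsets fail fast", {
  enc <- mk_enc("dat")
  enc$off_proj$b[] <- Inf
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  expect_error(ripedetr:::dat_attention(enc, x), "non-finite")
})
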