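test_that("patch filter weights are softmax-normalized and globally derived", {
  set.seed(1)
  cfg <- spectralflow_config(4, patch_size = 3, reduction = 2)
  m <- new_spectralflow(cfg)

  # zero input with zero biases: softmax of zeros is uniform
  w0 <- patch_filter_weights(array(0, dim = c(5, 5, 4, 2)), m)
  expect_equal(dim(w0), c(9, 2, 2))
  expect_equal(as.vector(w0), rep(1 / 9, 9 * 2 * 2))

  # any input: each (channel, image) slice sums to one
  x <- rand_fmap(6, 5, 4, 3)
  w <- patch_filter_weights(x, m)
  expect_equal(as.vector(apply(w, c(2, 3), sum)), rep(1, 6))
  expect_true(all(w >= 0))

  # forced pre-softmax logits (0, ln 2, ln 2, 0) -> (1/6, 2/6, 2/6, 1/6)
  cfg2 <- spectralflow_config(2, patch_size = 2, reduction = 2)
  m2 <- new_spectralflow(cfg2)
  m2$filtergen$w$v[] <- 0
  m2$filtergen$b$v <- c(0, log(2), log(2), 0)
  w2 <- patch_filter_weights(rand_fmap(4, 4, 2, 1), m2)
  expect_equal(as.vector(w2), c(1, 2, 2, 1) / 6, tolerance = 1e-12)

  expect_error(patch_filter_weights(rand_fmap(4, 4, 3, 1), m), "channel")
})

test_that("patch smoothing matches the brute-force oracle", {
  set.seed(2)
  for (k in c(1L, 2L, 3L, 5L)) {
    for (hw in list(c(6, 6), c(7, 7), c(7, 5))) {
      x <- rand_fmap(hw[1], hw[2], 2, 2)
      wts <- array(runif(k * k * 2 * 2), dim = c(k * k, 2, 2))
      wts <- sweep(wts, c(2, 3), apply(wts, c(2, 3), sum), `/`)
      expect_equal(smooth(x, wts, k), oracle_smooth(x, wts, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("patch smoothing special cases", {
  set.seed(3)
  k <- 3L
  wts <- array(runif(9 * 1 * 1), dim = c(9, 1, 1)); wts <- wts / sum(wts)
  const <- array(2.5, dim = c(6, 6, 1, 1))
  expect_equal(smooth(const, wts, k), const)          # convex combination
  x <- rand_fmap(6, 6, 1, 1)
  unif <- array(1 / 9, dim = c(9, 1, 1))
  sm <- smooth(x, unif, k)
  for (bh in 1:2) for (bw in 1:2) {
    rows <- (bh - 1) * 3 + 1:3; cols <- (bw - 1) * 3 + 1:3
    expect_equal(sm[rows, cols, 1, 1],
                 matrix(mean(x[rows, cols, 1, 1]), 3, 3))
  }
  expect_identical(smooth(x, array(1, c(1, 1, 1)), 1L), x)  # k = 1 identity
})

test_that("decomposition reconstructs the input exactly", {
  set.seed(4)
  cfg <- spectralflow_config(6, patch_size = 3, reduction = 2)
  m <- new_spectralflow(cfg)
  x <- rand_fmap(5, 7, 6, 2)
  d <- spectralflow_forward(x, m, decomposition = TRUE)
  expect_equal(d$x_la_proj + d$x_h, x, tolerance = 1e-14)
  # zero projection weights: the residue is the input itself
  zero_params(m$proj)
  r <- decompose(x, d$x_la, m)
  expect_identical(r$x_h, x)
  expect_true(all(r$x_la_proj == 0))
})

test_that("stream attention fuses the two streams convexly", {
  set.seed(5)
  cfg <- spectralflow_config(4, patch_size = 3, reduction = 2)
  m <- new_spectralflow(cfg)
  a <- rand_fmap(3, 3, 4, 2); b <- rand_fmap(3, 3, 4, 2)
  r <- stream_fuse(a, b, m, parts = TRUE)
  expect_equal(r$a_l + r$a_h, array(1, dim = dim(r$a_l)))
  expect_true(all(r$a_l > 0 & r$a_l < 1))

  # zero attention logits -> both weights exactly 1/2
  for (l in list(m$att_l, m$att_h)) zero_params(l)
  r2 <- stream_fuse(a, b, m, parts = TRUE)
  expect_equal(as.vector(r2$a_l), rep(0.5, length(r2$a_l)))

  # zero streams with zero-bias fusion conv map to zero
  z <- array(0, dim = c(3, 3, 4, 2))
  expect_true(all(stream_fuse(z, z, m) == 0))

  # saturated sigmoid attention selects channel 0 from the low stream and
  # channel 1 from the high stream under an identity mixing conv
  cfg3 <- spectralflow_config(2, patch_size = 3, reduction = 2,
                              stream_norm = "sigmoid")
  m3 <- new_spectralflow(cfg3)
  zero_params(m3$att_l); zero_params(m3$att_h)
  m3$att_l$b$v <- c(40, -40)   # a_l ~ (1, 0)
  m3$att_h$b$v <- c(-40, 40)   # a_h ~ (0, 1)
  m3$fuse$w$v[] <- 0
  m3$fuse$w$v[1, 1, 1, 1] <- 1; m3$fuse$w$v[1, 1, 2, 2] <- 1
  lo <- rand_fmap(1, 1, 2, 1); hi <- rand_fmap(1, 1, 2, 1)
  out <- stream_fuse(lo, hi, m3)
  expect_equal(out[1, 1, 1, 1], lo[1, 1, 1, 1], tolerance = 1e-8)
  expect_equal(out[1, 1, 2, 1], hi[1, 1, 2, 1], tolerance = 1e-8)

  expect_error(stream_fuse(a, rand_fmap(2, 3, 4, 2), m), "mismatch")
})

test_that("full forward preserves shape, maps zero to zero, stays finite", {
  set.seed(6)
  for (sh in list(c(7, 7), c(5, 8), c(1, 1), c(4, 4))) {
    cfg <- spectralflow_config(6, patch_size = 3, reduction = 2)
    m <- new_spectralflow(cfg)
    x <- rand_fmap(sh[1], sh[2], 6, 2)
    y <- spectralflow_forward(x, m)
    expect_equal(dim(y), dim(x))
    expect_true(all(is.finite(y)))
    expect_true(all(spectralflow_forward(array(0, dim = dim(x)), m) == 0))
  }
  # patch size 5 as the alternative configuration
  m5 <- new_spectralflow(spectralflow_config(4, patch_size = 5, reduction = 2))
  x <- rand_fmap(7, 7, 4, 1)
  expect_equal(dim(spectralflow_forward(x, m5)), dim(x))
})

test_that("profiled MACs grow linearly in the spatial extent", {
  set.seed(7)
  C <- 16L; r <- 2L; k <- 3L
  m <- new_spectralflow(spectralflow_config(C, patch_size = k, reduction = r))
  m1 <- count_macs(m, c(7, 7))
  m2 <- count_macs(m, c(7, 14))
  m3 <- count_macs(m, c(7, 21))
  # equal increments per extra 7x7 tile, equal to the closed-form
  # per-pixel cost of the three full-resolution 1x1 convolutions
  Cr <- C / r
  per_pixel <- C * Cr + Cr * C + C * C
  expect_identical(m2 - m1, per_pixel * 49)
  expect_identical(m3 - m2, per_pixel * 49)
})

test_that("spectralflow parameter count matches the closed form", {
  C <- 512L; r <- 2L; k <- 3L
  m <- new_spectralflow(spectralflow_config(C))
  Cr <- C / r; k2 <- k^2
  expected <- (C * Cr + Cr) + (C * Cr * k2 + Cr * k2) + (Cr * C + C) +
    2 * (C * C + C) + (C * C + C)
  expect_identical(count_params(m), as.numeric(expected))
})
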