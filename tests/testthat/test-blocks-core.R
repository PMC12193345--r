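# Building blocks: DSConv, PoolFormer, C3k2 and PF_C3k2.

test_that("dsconv preserves spatial size, maps channels, and is linear in its weights", {
  set.seed(1)
  x <- rand_fm(8, 8, 4)
  mod <- new_dsconv_block(block_config(4, 8))
  y <- dsconv_forward(x, module = mod)
  expect_equal(dim(y), c(8, 8, 8))

  # all weights and biases zero -> output identically zero
  z <- new_dsconv_block(block_config(4, 8))
  zero_conv(z$dw); zero_conv(z$pw)
  expect_true(all(dsconv_forward(x, module = z) == 0))

  # channel mismatch is a configuration error
  expect_error(dsconv_forward(x, module = new_dsconv_block(block_config(5, 8))),
               "channels")
})

test_that("dsconv with a centered delta depthwise kernel and identity pointwise is the identity", {
  set.seed(2)
  x <- rand_fm(6, 6, 3)
  m <- new_dsconv_block(block_config(3, 3), act = "none")
  m$dw$W[] <- 0
  m$dw$W[2, 2, ] <- 1   # centered delta per channel
  m$dw$b[] <- 0
  m$pw$W[] <- 0
  diag(m$pw$W) <- 1     # identity channel mixing
  m$pw$b[] <- 0
  expect_equal(dsconv_forward(x, module = m), x, tolerance = 1e-12)
})

test_that("dsconv forward matches the loop-based oracle", {
  set.seed(3)
  x <- rand_fm(7, 5, 3)
  m <- new_dsconv_block(block_config(3, 6))
  expect_equal(dsconv_forward(x, module = m), oracle_dsconv(m, x),
               tolerance = 1e-10)
})

test_that("poolformer block is the identity on constant input through stage 1, and exactly with a zeroed MLP", {
  cfg <- block_config(5, 5)
  m <- new_poolformer_block(cfg)
  xc <- feature_map(3.7, 6, 6, 5)
  # constant input: valid-divisor pooled mean of a constant equals the
  # constant, so the token mixer contributes exactly zero
  t1 <- m$ln1$forward(xc)
  expect_equal(pdayolo:::avgpool3_valid(t1), t1, tolerance = 1e-12)
  # additionally zero the MLP output layer -> whole block is the identity
  zero_conv(m$fc2)
  expect_equal(poolformer_forward(xc, module = m), xc, tolerance = 1e-12)
})

test_that("poolformer forward matches an independent step-by-step oracle", {
  set.seed(4)
  x <- rand_fm(6, 6, 8)
  m <- new_poolformer_block(block_config(8, 8, mlp_expansion = 2))
  expect_equal(poolformer_forward(x, module = m), oracle_poolformer(m, x),
               tolerance = 1e-8)
})

test_that("poolformer requires matching channel counts for its residuals", {
  expect_error(new_poolformer_block(block_config(4, 8)), "in_channels == out_channels")
})

test_that("C3k2 routing: mode_flag selects C3k vs Bottleneck; PF variant selects PF_C3k vs PoolFormer", {
  base_f <- new_c3k2_block(block_config(16, 16, mode_flag = FALSE))
  base_t <- new_c3k2_block(block_config(16, 16, mode_flag = TRUE))
  pf_f <- new_pf_c3k2_block(block_config(16, 16, mode_flag = FALSE))
  pf_t <- new_pf_c3k2_block(block_config(16, 16, mode_flag = TRUE))
  expect_true("bottleneck" %in% module_census(base_f))
  expect_false("c3k" %in% module_census(base_f))
  expect_true("c3k" %in% module_census(base_t))
  expect_true("poolformer" %in% module_census(pf_f))
  expect_false("bottleneck" %in% module_census(pf_f))
  expect_true("pf_c3k" %in% module_census(pf_t))
  expect_false("c3k" %in% module_census(pf_t))
})

test_that("C3k2 and PF_C3k2 preserve shape on 16x16x64", {
  set.seed(5)
  x <- rand_fm(16, 16, 64)
  expect_equal(dim(baseline_c3k2_forward(x, block_config(64, 64))), c(16, 16, 64))
  expect_equal(dim(pf_c3k2_forward(x, block_config(64, 64, mode_flag = TRUE))),
               c(16, 16, 64))
})

test_that("a zeroed Bottleneck with active skip passes features unchanged", {
  set.seed(6)
  x <- rand_fm(5, 5, 8)
  b <- pdayolo:::new_bottleneck(8, 8, shortcut = TRUE, e = 0.5)
  zero_conv(b$cv1); zero_conv(b$cv2)
  expect_equal(b$forward(x), x, tolerance = 1e-12)
})

test_that("PF_C3k2(false) costs fewer FLOPs per block than baseline C3k2(false)", {
  for (ch in c(16L, 64L, 128L)) {
    base <- new_c3k2_block(block_config(ch, ch, mode_flag = FALSE))
    pf <- new_pf_c3k2_block(block_config(ch, ch, mode_flag = FALSE))
    expect_lt(pf$flops(20, 20)$flops, base$flops(20, 20)$flops)
  }
})

test_that("stride-1 blocks preserve spatial size on non-square inputs", {
  set.seed(7)
  x <- rand_fm(9, 6, 8)
  mods <- list(new_dsconv_block(block_config(8, 8)),
               new_poolformer_block(block_config(8, 8)),
               new_c3k2_block(block_config(8, 8)),
               new_pf_c3k2_block(block_config(8, 8)),
               new_efe_block(8))
  for (m in mods) expect_equal(dim(m$forward(x))[1:2], c(9, 6))
})

test_that("block forwards match the loop oracle on random small inputs", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- rand_fm(8, 8, 8)
    m1 <- new_c3k2_block(block_config(8, 8, mode_flag = FALSE))
    y1 <- m1$forward(x)
    # oracle: cv1 -> split -> bottleneck chain -> concat -> cv2
    y0 <- oracle_conv(m1$cv1, x)
    a <- y0[, , 1:m1$ch, drop = FALSE]
    b <- y0[, , m1$ch + 1:m1$ch, drop = FALSE]
    bn <- m1$blocks[[1]]
    c3 <- oracle_conv(bn$cv2, oracle_conv(bn$cv1, b)) + b
    z <- array(c(a, b, c3), dim = c(8, 8, 3 * m1$ch))
    expect_equal(y1, oracle_conv(m1$cv2, z), tolerance = 1e-8)
  }
})
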