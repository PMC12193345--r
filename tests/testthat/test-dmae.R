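# DMAE: EFE identities, branch behavior, CWG weights, full-module oracle.

test_that("EFE edge map is exactly zero on constant input, including borders", {
  xc <- feature_map(4.2, 7, 7, 3)
  expect_true(all(efe_forward(xc, edge_only = TRUE) == 0))
})

test_that("EFE with a zeroed DSConv adds exactly 0.5 everywhere", {
  set.seed(21)
  x <- rand_fm(6, 6, 4)
  m <- new_efe_block(4)
  zero_conv(m$ds$dw); zero_conv(m$ds$pw)
  expect_equal(efe_forward(x, module = m), x + 0.5, tolerance = 1e-12)
})

test_that("EFE impulse arithmetic: center 9 on a 5x5 zero map", {
  x <- feature_map(0, 5, 5, 1)
  x[3, 3, 1] <- 9
  edge <- efe_forward(x, edge_only = TRUE)
  expect_equal(edge[3, 3, 1], 8)           # 9 - mean(3x3) = 9 - 1
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    expect_equal(edge[3 + dy, 3 + dx, 1], -1)  # 0 - 1
  }
  expect_true(all(edge[c(1, 5), , 1] == 0))    # >= 2 cells away
  expect_true(all(edge[, c(1, 5), 1] == 0))
})

test_that("EFE is a high-pass filter: step-edge response peaks within one cell of the discontinuity", {
  x <- feature_map(0, 6, 10, 1)
  x[, 6:10, 1] <- 1   # vertical step between columns 5 and 6
  edge <- abs(efe_forward(x, edge_only = TRUE))
  peak_cols <- unique(apply(edge[, , 1], 1, which.max))
  expect_true(all(peak_cols %in% 5:6))
  expect_true(all(edge[, c(1:3, 8:10), 1] < max(edge) / 10))
})

test_that("CWG: zero-initialized final layer gives all weights 0.5; outputs always in (0,1); spatial permutation invariance", {
  set.seed(22)
  cfg <- dmae_config(8, feat_rls = c(3L, 6L))
  x <- rand_fm(6, 6, 8)
  m0 <- pdayolo:::new_cwg(cfg)
  zero_conv(m0$fc2)
  w0 <- cwg_forward(x, module = m0)
  expect_equal(w0$w_local, 0.5)
  expect_equal(w0$w_edge, rep(0.5, 2))

  m <- pdayolo:::new_cwg(cfg)
  w <- m$forward(x)
  expect_length(w, 3)
  expect_true(all(w > 0 & w < 1))
  # permute spatial cells: the global mean is unchanged
  perm <- sample(36)
  xp <- x
  for (ci in 1:8) xp[, , ci] <- matrix(as.numeric(x[, , ci])[perm], 6, 6)
  expect_equal(m$forward(xp), w, tolerance = 1e-12)
})

test_that("edge-aware branch shape contract and degenerate-resolution error", {
  set.seed(23)
  cfg <- dmae_config(16, feat_rls = c(3L, 6L, 9L, 12L), reduction = 4L)
  x <- rand_fm(24, 24, 16)
  y <- edge_branch_forward(x, 3L, cfg)
  expect_equal(dim(y), c(24, 24, 4))
  expect_error(edge_branch_forward(rand_fm(8, 8, 16), 12L, cfg), "exceeds")
})

test_that("edge-aware branch maps constant inputs to spatially constant outputs", {
  set.seed(24)
  cfg <- dmae_config(8, feat_rls = c(3L, 6L), reduction = 2L)
  m <- pdayolo:::new_edge_branch(cfg, 3L)
  # biases are randomly nonzero already via construction; set some explicitly
  m$reduce$b <- rnorm(4)
  xc <- feature_map(1.3, 12, 12, 8)
  y <- m$forward(xc)
  for (ci in seq_len(dim(y)[3])) {
    expect_lt(max(y[, , ci]) - min(y[, , ci]), 1e-10)
  }
  expect_equal(y, oracle_edge_branch(m, xc), tolerance = 1e-8)
})

test_that("DMAE preserves shape and reduces to zero when branch weights are forced to zero", {
  set.seed(25)
  cfg <- dmae_config(12, feat_rls = c(3L, 6L, 9L, 12L), reduction = 3L)
  x <- rand_fm(24, 24, 12)
  m <- new_dmae_block(cfg)
  expect_equal(dim(dmae_forward(x, module = m)), dim(x))
  # zero weights -> concatenation is zero -> fusion of zero with zero bias is zero
  m$cwg$forward <- function(x) rep(0, cfg$n + 1)
  m$fuse$b[] <- 0
  expect_true(all(dmae_forward(x, module = m) == 0))
  # channel mismatch is a configuration error
  expect_error(dmae_forward(rand_fm(8, 8, 5), module = m), "channels")
})

test_that("branch weights scale the pre-fusion contributions linearly", {
  set.seed(26)
  cfg <- dmae_config(6, feat_rls = c(2L, 4L), reduction = 2L)
  m <- new_dmae_block(cfg)
  # make the fusion layer purely linear so the scaling is observable
  m$fuse$b[] <- 0
  m$fuse$act <- "none"
  x <- rand_fm(8, 8, 6)
  force_w <- function(w) { m$cwg$forward <- function(x) w; dmae_forward(x, module = m) }
  for (branch in 1:3) {
    w1 <- rep(0, 3); w1[branch] <- 1
    wh <- w1 / 2
    expect_equal(force_w(wh), force_w(w1) / 2, tolerance = 1e-10)
  }
})

test_that("DMAE forward equals the independent loop-based composition oracle", {
  for (seed in 1:2) {
    set.seed(seed * 31)
    cfg <- dmae_config(8, feat_rls = c(2L, 3L, 4L), reduction = 2L)
    m <- new_dmae_block(cfg)
    x <- rand_fm(8, 8, 8)
    expect_equal(dmae_forward(x, module = m), oracle_dmae(m, x), tolerance = 1e-5)
  }
})

test_that("dmae_config validates its invariants", {
  expect_error(dmae_config(8, feat_rls = c(3L, 3L)), "increasing")
  expect_error(dmae_config(8, feat_rls = c(6L, 3L)), "increasing")
  cfg <- dmae_config(8)
  expect_equal(cfg$feat_rls, c(3L, 6L, 9L, 12L))
  expect_equal(cfg$n, 4L)
  expect_equal(cfg$out_channels, cfg$in_channels)
})
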