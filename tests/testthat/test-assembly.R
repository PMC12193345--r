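# Detector assembly: variant census, shape contracts, FLOPs accounting,
# build purity, prediction plumbing.

test_that("variant parsing covers all eight combinations", {
  expect_equal(parse_variant("baseline"), model_variant())
  expect_equal(parse_variant("pf,dmae,aifi"), model_variant(TRUE, TRUE, TRUE))
  expect_equal(parse_variant("aifi"), model_variant(aifi = TRUE))
  expect_error(parse_variant("pf,bogus"), "unknown variant")
})

test_that("baseline census has C3k2 and SPPF; full variant replaces them and inserts DMAE", {
  base <- build_model(model_variant(), seed = 1)
  cb <- model_census(base)
  expect_gt(cb[["c3k2"]], 0)
  expect_equal(cb[["sppf"]], 1)
  expect_false(any(c("pf_c3k2", "dmae", "aifi") %in% names(cb)))

  full <- build_model(model_variant(TRUE, TRUE, TRUE), seed = 1)
  cf <- model_census(full)
  expect_false("c3k2" %in% names(cf))
  expect_false("sppf" %in% names(cf))
  expect_equal(cf[["pf_c3k2"]], 8)
  expect_equal(cf[["aifi"]], 1)
  expect_equal(cf[["dmae"]], 3)
})

test_that("forward pass at 640 yields three prediction maps at strides 8/16/32", {
  m <- build_model(model_variant(), seed = 2, imgsz = 640)
  x <- array(runif(640 * 640 * 3), dim = c(640, 640, 3))
  outs <- pdayolo:::model_forward(m, x)
  expect_length(outs, 3)
  expect_equal(dim(outs[[1]]$box)[1:2], c(80, 80))
  expect_equal(dim(outs[[2]]$box)[1:2], c(40, 40))
  expect_equal(dim(outs[[3]]$box)[1:2], c(20, 20))
  expect_equal(dim(outs[[1]]$cls)[3], 5)
})

test_that("closed-form FLOPs of single convolutions", {
  c1 <- pdayolo:::new_conv(256, 256, k = 1)
  expect_equal(c1$flops(20, 20)$flops, 2 * 400 * 256 * 256)  # 52,428,800
  c2 <- pdayolo:::new_conv(3, 16, k = 3, s = 2)
  r <- c2$flops(640, 640)
  expect_equal(r$h, 320); expect_equal(r$w, 320)
  expect_equal(r$flops, 2 * 320 * 320 * 16 * 3 * 9)          # 88,473,600
})

test_that("count_flops is architecture-only: invariant to seed and parameter values", {
  m1 <- build_model(model_variant(TRUE, FALSE, TRUE), seed = 1)
  m2 <- build_model(model_variant(TRUE, FALSE, TRUE), seed = 999)
  expect_identical(count_flops(m1)$gflops, count_flops(m2)$gflops)
})

test_that("module FLOPs deltas are additive across all eight combinations", {
  led <- flops_ledger(seed = 1)
  base <- led$gflops[!led$pf_c3k2 & !led$dmae & !led$aifi]
  d_pf <- led$gflops[led$pf_c3k2 & !led$dmae & !led$aifi] - base
  d_dm <- led$gflops[!led$pf_c3k2 & led$dmae & !led$aifi] - base
  d_ai <- led$gflops[!led$pf_c3k2 & !led$dmae & led$aifi] - base
  for (i in seq_len(nrow(led))) {
    pred <- base + led$pf_c3k2[i] * d_pf + led$dmae[i] * d_dm + led$aifi[i] * d_ai
    expect_lt(abs(led$gflops[i] - pred), 0.05)
    expect_lt(abs(led$gflops[i] - pred), 1e-9)  # exact by module independence
  }
  expect_lt(d_pf, 0)   # PoolFormer substitution reduces total FLOPs
  expect_gt(d_dm, 0)
  expect_gt(d_ai, 0)
})

test_that("build_model is pure: same variant and seed give an identical parameter checksum", {
  s1 <- model_param_sum(build_model(model_variant(TRUE, TRUE, TRUE), seed = 5))
  s2 <- model_param_sum(build_model(model_variant(TRUE, TRUE, TRUE), seed = 5))
  s3 <- model_param_sum(build_model(model_variant(TRUE, TRUE, TRUE), seed = 6))
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})

test_that("NMS keeps the higher-confidence duplicate and respects the IoU threshold", {
  df <- data.frame(class_id = 0L, x1 = c(10, 10), y1 = c(10, 10),
                   x2 = c(30, 30), y2 = c(30, 30), conf = c(0.9, 0.8))
  kept <- pdayolo:::nms_boxes(df, 0.45)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$conf, 0.9)
  # different classes are never suppressed against each other
  df$class_id <- c(0L, 1L)
  expect_equal(nrow(pdayolo:::nms_boxes(df, 0.45)), 2)
})

test_that("prediction respects thresholds and the clipping contract", {
  m <- build_model(model_variant(), seed = 3, imgsz = 96)
  img <- array(runif(96 * 96 * 3), dim = c(96, 96, 3))
  expect_equal(nrow(predict_image(m, img, conf_threshold = 1.0)), 0)
  det <- predict_image(m, img, conf_threshold = 0.0001)
  if (nrow(det) > 0) {
    x1 <- det$cx - det$w / 2; x2 <- det$cx + det$w / 2
    y1 <- det$cy - det$h / 2; y2 <- det$cy + det$h / 2
    expect_true(all(x1 >= -1e-9 & x2 <= 1 + 1e-9 & x1 < x2))
    expect_true(all(y1 >= -1e-9 & y2 <= 1 + 1e-9 & y1 < y2))
    expect_true(all(det$conf >= 0 & det$conf <= 1))
  }
  expect_error(predict_image(m, "no-such-file.png"), "cannot read")
})

test_that("model forward/backward matches per-parameter finite differences end to end", {
  set.seed(71)
  m <- build_model(model_variant(TRUE, TRUE, TRUE), num_classes = 2, seed = 9,
                   imgsz = 64)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  ann <- tibble::tibble(class_id = 0L, cx = 0.4, cy = 0.5, w = 0.2, h = 0.2)
  lossfn <- function() {
    outs <- pdayolo:::model_forward(m, img, keep = TRUE)
    pdayolo:::detection_loss(outs, ann, 64, m$strides, m$nc)
  }
  dl <- lossfn()
  pdayolo:::model_zero_grad(m)
  pdayolo:::model_backward(m, dl$grads)
  leaves <- unlist(lapply(pdayolo:::layer_modules(m), pdayolo:::mod_leaves),
                   recursive = FALSE)
  for (li in sample(length(leaves), 6)) {
    leaf <- leaves[[li]]
    p <- sample(leaf$param_names, 1)
    i <- sample(length(leaf[[p]]), 1)
    g_ana <- leaf$grad[[p]][i]
    eps <- 1e-4
    orig <- leaf[[p]][i]
    leaf[[p]][i] <- orig + eps; lp <- lossfn()$loss
    leaf[[p]][i] <- orig - eps; lm <- lossfn()$loss
    leaf[[p]][i] <- orig
    g_num <- (lp - lm) / (2 * eps)
    expect_lt(abs(g_ana - g_num) / max(1e-6, abs(g_ana) + abs(g_num)), 5e-3)
  }
})
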