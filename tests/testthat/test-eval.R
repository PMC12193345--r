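# Detection metrics: IoU, matching, P/R/F1, AP, mAP, timing.

test_that("box IoU: self-overlap, disjoint boxes, corner-overlap arithmetic", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7, tolerance = 1e-9)
  # center/size layout agrees with the corner layout
  expect_equal(box_iou(c(1, 1, 2, 2), c(2, 2, 2, 2), format = "cxcywh"),
               box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), tolerance = 1e-12)
  expect_error(box_iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "positive area")
})

test_that("greedy matching: single match, one-to-one constraint, threshold rejection", {
  gt <- tibble::tibble(cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  d_hit <- tibble::tibble(cx = 0.52, cy = 0.5, w = 0.2, h = 0.2, conf = 0.9)
  m <- match_detections(d_hit, gt, 0.5)
  expect_equal(m$counts, list(tp = 1L, fp = 0L, fn = 0L))

  d_two <- dplyr::bind_rows(d_hit, dplyr::mutate(d_hit, conf = 0.8))
  m2 <- match_detections(d_two, gt, 0.5)
  expect_equal(m2$counts, list(tp = 1L, fp = 1L, fn = 0L))
  expect_equal(m2$tp_flags, c(TRUE, FALSE))

  d_low <- tibble::tibble(cx = 0.62, cy = 0.62, w = 0.2, h = 0.2, conf = 0.9)
  iou <- box_iou(as.numeric(d_low[1, 1:4]), as.numeric(gt[1, ]), "cxcywh")
  expect_lt(iou, 0.5)
  m3 <- match_detections(d_low, gt, 0.5)
  expect_equal(m3$counts, list(tp = 0L, fp = 1L, fn = 1L))
})

test_that("precision, recall and F1 follow the exact formulas with degenerate conventions", {
  r <- precision_recall_f1(8, 2, 2)
  expect_equal(r, list(precision = 0.8, recall = 0.8, f1 = 0.8))
  r2 <- precision_recall_f1(9, 1, 0)
  # P = 0.9, R = 1 -> check harmonic mean; and the worked pair P=0.9, R=0.8
  expect_equal(r2$f1, 2 * 0.9 / 1.9, tolerance = 1e-12)
  expect_equal(2 * 0.9 * 0.8 / (0.9 + 0.8), 0.847059, tolerance = 1e-6)
  expect_equal(precision_recall_f1(0, 0, 5), list(precision = 0, recall = 0, f1 = 0))
})

test_that("average precision: perfect detector, worked envelope and 101-point examples", {
  expect_equal(average_precision(rep(TRUE, 4), NULL, 4), 1.0, tolerance = 1e-9)
  flags <- c(TRUE, FALSE, TRUE)  # already in decreasing-confidence order
  expect_equal(average_precision(flags, NULL, 2, interpolation = "envelope"),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-9)
  expect_equal(average_precision(flags, NULL, 2, interpolation = "coco101"),
               (51 * 1 + 50 * (2 / 3)) / 101, tolerance = 1e-9)
  expect_equal((51 * 1 + 50 * (2 / 3)) / 101, 0.835, tolerance = 1e-3)
})

test_that("adding a true positive never decreases AP; mAP@0.5:0.95 <= mAP@0.5", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    flags <- runif(n) < 0.6
    conf <- runif(n)
    n_gt <- sum(flags) + sample(0:3, 1)
    if (n_gt == 0) n_gt <- 1
    ap0 <- average_precision(flags, conf, n_gt + 1)
    ap1 <- average_precision(c(flags, TRUE), c(conf, runif(1)), n_gt + 1)
    expect_gte(ap1 + 1e-12, ap0)
  }
})

test_that("full evaluator agrees with an independent threshold-sweep reference on random scenes", {
  set.seed(52)
  for (rep in 1:4) {
    n_gt <- sample(3:8, 1)
    gt <- tibble::tibble(image = 1L, class_id = 0L,
                         cx = runif(n_gt, 0.2, 0.8), cy = runif(n_gt, 0.2, 0.8),
                         w = runif(n_gt, 0.05, 0.2), h = runif(n_gt, 0.05, 0.2))
    # detections: jittered truths plus planted false positives
    dets <- dplyr::mutate(gt,
      cx = cx + runif(n_gt, -0.02, 0.02), cy = cy + runif(n_gt, -0.02, 0.02),
      conf = runif(n_gt, 0.5, 1))
    fps <- tibble::tibble(image = 1L, class_id = 0L,
                          cx = runif(2, 0.2, 0.8), cy = runif(2, 0.2, 0.8),
                          w = 0.08, h = 0.08, conf = runif(2, 0, 0.6))
    dets <- dplyr::bind_rows(dets, fps)
    ev <- evaluate_detections(dets, gt, iou_thresholds = 0.5,
                              interpolation = "envelope")
    ref <- reference_ap_envelope(as.data.frame(dets), as.data.frame(gt), 0.5)
    expect_equal(ev$map50, ref, tolerance = 1e-6)
  }
})

test_that("mAP aggregation: unanimity, simple mean, and threshold ordering", {
  expect_equal(mean_ap(rep(1, 5))$map50, 1)
  expect_equal(mean_ap(c(0.8, 0.6))$map50, 0.7)
  set.seed(53)
  gt <- tibble::tibble(image = rep(1:3, each = 4), class_id = rep(0:1, 6),
                       cx = runif(12, 0.2, 0.8), cy = runif(12, 0.2, 0.8),
                       w = runif(12, 0.08, 0.2), h = runif(12, 0.08, 0.2))
  dets <- dplyr::mutate(gt, cx = cx + runif(12, -0.03, 0.03),
                        cy = cy + runif(12, -0.03, 0.03), conf = runif(12))
  ev <- evaluate_detections(dets, gt)
  expect_lte(ev$map50_95, ev$map50 + 1e-12)
  expect_true(all(ev$per_class$ap >= 0 & ev$per_class$ap <= 1))
})

test_that("classes absent from ground truth are skipped and recorded", {
  gt <- tibble::tibble(image = 1L, class_id = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  dets <- tibble::tibble(image = 1L, class_id = c(0L, 3L), cx = 0.5, cy = 0.5,
                         w = 0.2, h = 0.2, conf = 0.9)
  ev <- evaluate_detections(dets, gt)
  expect_equal(ev$skipped_classes, 3L)
  expect_equal(sort(unique(ev$per_class$class_id)), 0L)
})

test_that("mean detection time: mean, singleton, constants, empty error", {
  expect_equal(mean_detection_time(c(4, 6)), 5)
  expect_equal(mean_detection_time(7.3), 7.3)
  expect_equal(mean_detection_time(rep(9.9, 100)), 9.9)
  expect_error(mean_detection_time(numeric()), "at least one")
})

test_that("tidy and glance on evaluation results return tibbles", {
  gt <- tibble::tibble(image = 1L, class_id = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  dets <- dplyr::mutate(gt, conf = 0.9)
  ev <- evaluate_detections(dets, gt, times_ms = c(5, 7))
  expect_s3_class(tidy(ev), "tbl_df")
  g <- glance(ev)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$mean_detection_time_ms, 6)
  expect_equal(g$map50, 1)
})
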