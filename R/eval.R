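# Detection metrics: IoU, greedy matching, precision/recall/F1, average
# precision by precision-recall integration (COCO-style 101-point grid by
# default, all-point envelope as an alternative), mAP@0.5 and mAP@0.5:0.95,
# and mean detection time.

#' Intersection over union of two boxes
#'
#' @param a,b numeric length-4 boxes. `format = "xyxy"` reads them as
#'   `(x1, y1, x2, y2)` corners; `format = "cxcywh"` as normalized
#'   center/size (the annotation convention).
#' @param format box layout.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b, format = c("xyxy", "cxcywh")) {
  format <- match.arg(format)
  if (format == "cxcywh") {
    a <- c(a[1] - a[3] / 2, a[2] - a[4] / 2, a[1] + a[3] / 2, a[2] + a[4] / 2)
    b <- c(b[1] - b[3] / 2, b[2] - b[4] / 2, b[1] + b[3] / 2, b[2] + b[4] / 2)
  }
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    stop("boxes must have positive area")
  iou_corner(a[1], a[2], a[3], a[4], b[1], b[2], b[3], b[4])
}

iou_matrix <- function(dets, gts) {
  nd <- nrow(dets); ng <- nrow(gts)
  m <- matrix(0, nd, ng)
  if (nd == 0 || ng == 0) return(m)
  dx1 <- dets$cx - dets$w / 2; dy1 <- dets$cy - dets$h / 2
  dx2 <- dets$cx + dets$w / 2; dy2 <- dets$cy + dets$h / 2
  gx1 <- gts$cx - gts$w / 2; gy1 <- gts$cy - gts$h / 2
  gx2 <- gts$cx + gts$w / 2; gy2 <- gts$cy + gts$h / 2
  for (j in seq_len(ng)) {
    m[, j] <- iou_corner(dx1, dy1, dx2, dy2, gx1[j], gy1[j], gx2[j], gy2[j])
  }
  m
}

#' Greedy detection-to-truth matching (single class)
#'
#' Detections are visited in order of decreasing confidence; each claims the
#' highest-IoU still-unmatched ground truth provided IoU >= `iou_threshold`
#' (a true positive), otherwise it is a false positive. Each ground truth is
#' used at most once; leftover ground truths are false negatives.
#'
#' @param detections tibble `cx, cy, w, h, conf` (one class).
#' @param ground_truth tibble `cx, cy, w, h` (same class).
#' @param iou_threshold matching threshold.
#' @return list with `counts` (`tp`, `fp`, `fn`), `tp_flags` (logical, in
#'   decreasing-confidence order) and `conf` (the matching confidence order).
#' @export
match_detections <- function(detections, ground_truth, iou_threshold = 0.5) {
  ord <- order(detections$conf, decreasing = TRUE)
  dets <- detections[ord, , drop = FALSE]
  ious <- iou_matrix(dets, ground_truth)
  ng <- nrow(ground_truth)
  used <- logical(ng)
  flags <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    if (ng == 0) break
    cand <- which(!used)
    if (length(cand) == 0) break
    j <- cand[which.max(ious[i, cand])]
    if (ious[i, j] >= iou_threshold) {
      flags[i] <- TRUE
      used[j] <- TRUE
    }
  }
  list(counts = list(tp = sum(flags), fp = sum(!flags), fn = sum(!used)),
       tp_flags = flags, conf = dets$conf)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`; the
#' degenerate zero-denominator cases are defined as 0.
#'
#' @param tp,fp,fn non-negative counts (or a list with those names as `tp`).
#' @return list with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp = NULL, fn = NULL) {
  if (is.list(tp)) { fp <- tp$fp; fn <- tp$fn; tp <- tp$tp }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1)
}

#' Average precision from ranked true-positive flags
#'
#' Sweeps the confidence ranking, builds the precision-recall curve and
#' integrates it, either on the 101-point recall grid (`"coco101"`, the
#' mAP@0.5:0.95 convention) or with the all-point envelope
#' (`"envelope"`).
#'
#' @param tp_flags logical vector of per-detection true-positive flags.
#' @param conf matching confidences (used only to order; pass flags already
#'   ordered and `conf = NULL` to keep the given order).
#' @param n_gt number of ground-truth objects (>= 1).
#' @param interpolation integration rule.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(tp_flags, conf = NULL, n_gt,
                              interpolation = c("coco101", "envelope")) {
  interpolation <- match.arg(interpolation)
  if (n_gt < 1) stop("average_precision needs n_gt >= 1")
  if (!is.null(conf)) tp_flags <- tp_flags[order(conf, decreasing = TRUE)]
  if (length(tp_flags) == 0) return(0)
  ctp <- cumsum(tp_flags)
  recall <- ctp / n_gt
  precision <- ctp / seq_along(tp_flags)
  # precision envelope: max precision at recall >= r
  penv <- rev(cummax(rev(precision)))
  if (interpolation == "coco101") {
    grid <- seq(0, 1, by = 0.01)
    pr <- vapply(grid, function(r) {
      ok <- which(recall >= r)
      if (length(ok) == 0) 0 else penv[ok[1]]
    }, numeric(1))
    mean(pr)
  } else {
    r_prev <- c(0, recall)
    sum((recall - r_prev[-length(r_prev)]) * penv)
  }
}

#' Mean average precision over classes and IoU thresholds
#'
#' @param ap_matrix numeric matrix of per-class APs (classes x thresholds)
#'   whose first column is IoU 0.5, or a vector of per-class APs at 0.5.
#' @return list with `map50` and (when thresholds span 0.5:0.95) `map50_95`.
#' @export
mean_ap <- function(ap_matrix) {
  if (is.vector(ap_matrix)) ap_matrix <- matrix(ap_matrix, ncol = 1)
  list(map50 = mean(ap_matrix[, 1]),
       map50_95 = mean(ap_matrix))
}

#' Mean detection time
#'
#' Arithmetic mean of per-image inference times in milliseconds.
#'
#' @param times_ms numeric vector, one entry per image.
#' @return mean time in ms.
#' @export
mean_detection_time <- function(times_ms) {
  if (length(times_ms) == 0) stop("mean_detection_time needs at least one time")
  mean(times_ms)
}

#' Evaluate detections against ground truth
#'
#' Class-wise evaluation with no cross-class matching: per class and IoU
#' threshold, detections are matched greedily per image, pooled, and
#' integrated into an AP. Classes absent from the ground truth are skipped
#' and recorded. Precision/recall/F1 are reported at IoU 0.5 for detections
#' above `conf_threshold`.
#'
#' @param detections tibble `image, class_id, cx, cy, w, h, conf`.
#' @param ground_truth tibble `image, class_id, cx, cy, w, h`.
#' @param iou_thresholds vector of IoU thresholds (default 0.5 to 0.95 by
#'   0.05).
#' @param interpolation AP integration rule, see [average_precision()].
#' @param conf_floor detections below this confidence are discarded first.
#' @param conf_threshold operating point for precision/recall/F1.
#' @param times_ms optional per-image times for the mean detection time.
#' @return a `pda_eval` object with per-class AP tibble, `map50`,
#'   `map50_95`, `precision`, `recall`, `f1`, and `mean_detection_time_ms`.
#' @export
evaluate_detections <- function(detections, ground_truth,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05),
                                interpolation = c("coco101", "envelope"),
                                conf_floor = 0.001, conf_threshold = 0.25,
                                times_ms = NULL) {
  interpolation <- match.arg(interpolation)
  if (!"image" %in% names(detections)) detections$image <- 1L
  if (!"image" %in% names(ground_truth)) ground_truth$image <- 1L
  detections <- detections[detections$conf >= conf_floor, , drop = FALSE]
  classes <- sort(unique(ground_truth$class_id))
  skipped <- sort(setdiff(unique(detections$class_id), classes))
  ap_rows <- list()
  counts050 <- c(tp = 0, fp = 0, fn = 0)
  pr_curves <- list()
  for (cl in classes) {
    gt_c <- ground_truth[ground_truth$class_id == cl, , drop = FALSE]
    det_c <- detections[detections$class_id == cl, , drop = FALSE]
    n_gt <- nrow(gt_c)
    for (thr in iou_thresholds) {
      flags <- logical(0); confs <- numeric(0)
      for (im in unique(c(gt_c$image, det_c$image))) {
        m <- match_detections(det_c[det_c$image == im, , drop = FALSE],
                              gt_c[gt_c$image == im, , drop = FALSE], thr)
        flags <- c(flags, m$tp_flags)
        confs <- c(confs, m$conf)
      }
      ap <- average_precision(flags, confs, n_gt, interpolation)
      ap_rows[[length(ap_rows) + 1L]] <-
        tibble::tibble(class_id = cl, iou = thr, ap = ap, n_gt = n_gt)
      if (abs(thr - 0.5) < 1e-9) {
        ord <- order(confs, decreasing = TRUE)
        ctp <- cumsum(flags[ord])
        pr_curves[[as.character(cl)]] <- tibble::tibble(
          class_id = cl, recall = ctp / n_gt,
          precision = ctp / seq_along(ctp))
        # operating-point counts at conf_threshold
        det_hi <- det_c[det_c$conf >= conf_threshold, , drop = FALSE]
        tp <- 0; fp <- 0; fn <- 0
        for (im in unique(c(gt_c$image, det_hi$image))) {
          m <- match_detections(det_hi[det_hi$image == im, , drop = FALSE],
                                gt_c[gt_c$image == im, , drop = FALSE], 0.5)
          tp <- tp + m$counts$tp; fp <- fp + m$counts$fp; fn <- fn + m$counts$fn
        }
        counts050 <- counts050 + c(tp = tp, fp = fp, fn = fn)
      }
    }
  }
  per_class <- dplyr::bind_rows(ap_rows)
  ap50 <- per_class$ap[abs(per_class$iou - 0.5) < 1e-9]
  prf <- precision_recall_f1(counts050[["tp"]], counts050[["fp"]], counts050[["fn"]])
  structure(list(
    per_class = per_class,
    map50 = mean(ap50),
    map50_95 = mean(vapply(classes, function(cl) {
      mean(per_class$ap[per_class$class_id == cl])
    }, numeric(1))),
    precision = prf$precision, recall = prf$recall, f1 = prf$f1,
    counts = as.list(counts050),
    mean_detection_time_ms = if (is.null(times_ms)) NA_real_
      else mean_detection_time(times_ms),
    skipped_classes = skipped,
    interpolation = interpolation,
    pr_curves = dplyr::bind_rows(pr_curves)),
    class = "pda_eval")
}

#' @export
print.pda_eval <- function(x, ...) {
  cat(sprintf("<pda_eval> mAP@0.5 %.4f | mAP@0.5:0.95 %.4f | P %.4f R %.4f F1 %.4f\n",
              x$map50, x$map50_95, x$precision, x$recall, x$f1))
  if (!is.na(x$mean_detection_time_ms))
    cat(sprintf("  mean detection time %.1f ms\n", x$mean_detection_time_ms))
  invisible(x)
}

#' @rdname evaluate_detections
#' @param x,object a `pda_eval` object.
#' @param ... unused.
#' @export
tidy.pda_eval <- function(x, ...) x$per_class

#' @rdname evaluate_detections
#' @export
glance.pda_eval <- function(x, ...) {
  tibble::tibble(map50 = x$map50, map50_95 = x$map50_95,
                 precision = x$precision, recall = x$recall, f1 = x$f1,
                 mean_detection_time_ms = x$mean_detection_time_ms)
}

#' @rdname evaluate_detections
#' @export
autoplot.pda_eval <- function(object, ...) {
  ggplot2::ggplot(object$pr_curves,
                  ggplot2::aes(x = .data$recall, y = .data$precision,
                               color = factor(.data$class_id))) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision", color = "class",
                  title = "Precision-recall at IoU 0.5") +
    ggplot2::theme_minimal()
}

#' Evaluate a model on a dataset split
#'
#' Runs [predict_image()] over every image of a manifest split, times the
#' forward+decode+NMS path per image, and calls [evaluate_detections()].
#'
#' @param model a `pda_model`.
#' @param manifest a `pda_manifest` (or path to its YAML).
#' @param split split name.
#' @param conf_floor,iou_nms prediction thresholds.
#' @param ... passed to [evaluate_detections()].
#' @return a `pda_eval` object.
#' @export
evaluate_model <- function(model, manifest, split = "test",
                           conf_floor = 0.001, iou_nms = 0.45, ...) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  img_dir <- manifest[[split]]$images
  files <- sort(list.files(img_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no images in split '", split, "'")
  det_rows <- list(); gt_rows <- list(); times <- numeric(length(files))
  for (i in seq_along(files)) {
    img <- read_image_png(files[i])
    t0 <- proc.time()[["elapsed"]]
    det <- predict_image(model, img, conf_threshold = conf_floor,
                         iou_threshold = iou_nms)
    times[i] <- (proc.time()[["elapsed"]] - t0) * 1000
    if (nrow(det) > 0) { det$image <- i; det_rows[[length(det_rows) + 1L]] <- det }
    lbl <- file.path(manifest[[split]]$labels,
                     sub("\\.png$", ".txt", basename(files[i])))
    gt <- read_yolo_labels(lbl)
    if (nrow(gt) > 0) { gt$image <- i; gt_rows[[length(gt_rows) + 1L]] <- gt }
  }
  evaluate_detections(dplyr::bind_rows(det_rows), dplyr::bind_rows(gt_rows),
                      conf_floor = conf_floor, times_ms = times, ...)
}
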