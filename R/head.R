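# Anchor-free detection head (three scales, strides 8/16/32). Per scale: a
# box branch predicting 4 * reg_max distribution-focal logits over the
# left/top/right/bottom cell-unit distances, and a class branch with
# depthwise-separable stages predicting per-class logits. Decoding takes the
# softmax expectation over the 16 DFL bins, offsets the cell-center anchors
# and multiplies by the stride.

DFL_BINS <- 16L

new_detect_head <- function(ch, nc) {
  m <- new_module_env("detect")
  m$nc <- as.integer(nc)
  c2 <- max(16L, ch[1] %/% 4L, 4L * DFL_BINS)
  c3 <- max(ch[1], min(m$nc, 100L))
  m$box <- lapply(ch, function(ci) {
    list(new_conv(ci, c2, k = 3L), new_conv(c2, c2, k = 3L),
         new_conv(c2, 4L * DFL_BINS, k = 1L, act = "none"))
  })
  m$cls <- lapply(ch, function(ci) {
    final <- new_conv(c3, nc, k = 1L, act = "none")
    final$b[] <- -4.6  # start near zero detection probability
    list(new_dwconv(ci, k = 3L), new_conv(ci, c3, k = 1L),
         new_dwconv(c3, k = 3L), new_conv(c3, c3, k = 1L), final)
  })
  m$children <- c(unlist(m$box, recursive = FALSE),
                  unlist(m$cls, recursive = FALSE))
  m$forward <- function(xs) {
    lapply(seq_along(xs), function(i) {
      b <- xs[[i]]
      for (mod in m$box[[i]]) b <- mod$forward(b)
      cl <- xs[[i]]
      for (mod in m$cls[[i]]) cl <- mod$forward(cl)
      list(box = b, cls = cl)
    })
  }
  m$backward <- function(dys) {
    lapply(seq_along(dys), function(i) {
      db <- dys[[i]]$box
      for (mod in rev(m$box[[i]])) db <- mod$backward(db)
      dc <- dys[[i]]$cls
      for (mod in rev(m$cls[[i]])) dc <- mod$backward(dc)
      db + dc
    })
  }
  m$flops_scale <- function(i, h, w) {
    f <- 0
    for (mod in m$box[[i]]) { r <- mod$flops(h, w); f <- f + r$flops }
    for (mod in m$cls[[i]]) { r <- mod$flops(h, w); f <- f + r$flops }
    # DFL expectation conv: reg_max MACs per side per anchor
    f + 2 * h * w * 4 * DFL_BINS
  }
  m
}

# Softmax expectation over DFL bins -> distances in cell units.
dfl_expect <- function(box_map) {
  d <- dim(box_map)
  n <- d[1] * d[2]
  logits <- array(box_map, dim = c(n, DFL_BINS, 4L))
  dist <- matrix(0, n, 4L)
  for (side in 1:4) {
    p <- softmax_rows(matrix(logits[, , side], n, DFL_BINS))
    dist[, side] <- p %*% (seq_len(DFL_BINS) - 1)
  }
  dist
}

# Decode one scale's raw maps into pixel-space boxes + class scores.
decode_scale <- function(out, stride, imgsz, nc) {
  d <- dim(out$box)
  n <- d[1] * d[2]
  dist <- dfl_expect(out$box)
  ay <- rep(seq_len(d[1]) - 0.5, times = d[2])
  ax <- rep(seq_len(d[2]) - 0.5, each = d[1])
  x1 <- (ax - dist[, 1]) * stride
  y1 <- (ay - dist[, 2]) * stride
  x2 <- (ax + dist[, 3]) * stride
  y2 <- (ay + dist[, 4]) * stride
  scores <- stats::plogis(matrix(out$cls, n, nc))
  list(x1 = x1, y1 = y1, x2 = x2, y2 = y2, scores = scores)
}

# Greedy class-wise non-maximum suppression on pixel-space corner boxes.
nms_boxes <- function(df, iou_threshold) {
  keep <- logical(nrow(df))
  for (cl in unique(df$class_id)) {
    idx <- which(df$class_id == cl)
    idx <- idx[order(df$conf[idx], decreasing = TRUE)]
    taken <- integer()
    for (i in idx) {
      ok <- TRUE
      for (j in taken) {
        iou <- iou_corner(df$x1[i], df$y1[i], df$x2[i], df$y2[i],
                          df$x1[j], df$y1[j], df$x2[j], df$y2[j])
        if (iou > iou_threshold) { ok <- FALSE; break }
      }
      if (ok) { keep[i] <- TRUE; taken <- c(taken, i) }
    }
  }
  df[keep, , drop = FALSE]
}

iou_corner <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  iw <- pmax(0, pmin(ax2, bx2) - pmax(ax1, bx1))
  ih <- pmax(0, pmin(ay2, by2) - pmax(ay1, by1))
  inter <- iw * ih
  union <- (ax2 - ax1) * (ay2 - ay1) + (bx2 - bx1) * (by2 - by1) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Run detection on one image
#'
#' Forward pass, DFL decode, confidence filtering and class-wise greedy NMS.
#' Returned boxes are clipped to the image and expressed in normalized
#' center/size coordinates.
#'
#' @param model a detector from [build_model()].
#' @param image an `h x w x 3` array in `[0, 1]`, or a path to a PNG file.
#' @param conf_threshold minimum class confidence kept.
#' @param iou_threshold IoU above which same-class boxes are suppressed.
#' @return tibble with `class_id`, `cx`, `cy`, `w`, `h`, `conf`.
#' @export
predict_image <- function(model, image, conf_threshold = 0.25,
                          iou_threshold = 0.45) {
  stopifnot(conf_threshold >= 0, conf_threshold <= 1,
            iou_threshold >= 0, iou_threshold <= 1)
  if (is.character(image)) image <- read_image_png(image)
  d <- dim(image)
  imgsz <- model$imgsz
  if (d[1] != imgsz || d[2] != imgsz) image <- bilinear_resize(image, imgsz, imgsz)
  outs <- model_forward(model, image)
  rows <- list()
  for (i in seq_along(outs)) {
    dec <- decode_scale(outs[[i]], model$strides[i], imgsz, model$nc)
    best <- max.col(dec$scores, ties.method = "first")
    conf <- dec$scores[cbind(seq_along(best), best)]
    sel <- which(conf >= conf_threshold)
    if (length(sel) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      class_id = best[sel] - 1L,
      x1 = pmin(pmax(dec$x1[sel], 0), imgsz), y1 = pmin(pmax(dec$y1[sel], 0), imgsz),
      x2 = pmin(pmax(dec$x2[sel], 0), imgsz), y2 = pmin(pmax(dec$y2[sel], 0), imgsz),
      conf = conf[sel])
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(class_id = integer(), cx = numeric(), cy = numeric(),
                          w = numeric(), h = numeric(), conf = numeric()))
  }
  df <- do.call(rbind, rows)
  df <- df[df$x2 > df$x1 & df$y2 > df$y1, , drop = FALSE]
  df <- nms_boxes(df, iou_threshold)
  tibble::tibble(class_id = as.integer(df$class_id),
                 cx = (df$x1 + df$x2) / 2 / imgsz,
                 cy = (df$y1 + df$y2) / 2 / imgsz,
                 w = (df$x2 - df$x1) / imgsz,
                 h = (df$y2 - df$y1) / imgsz,
                 conf = df$conf)
}
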