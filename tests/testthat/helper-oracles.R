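# Independent loop-based reference implementations used to cross-check the
# vectorized/Rcpp forward passes. Deliberately written with explicit loops
# and none of the package's kernel code.

rand_fm <- function(h, w, c, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(h * w * c), dim = c(h, w, c))
}

o_silu <- function(z) z / (1 + exp(-z))
o_gelu <- function(z) z * pnorm(z)
o_act <- function(z, act) switch(act, silu = o_silu(z), gelu = o_gelu(z),
                                 relu = pmax(z, 0), none = z,
                                 sigmoid = 1 / (1 + exp(-z)))

# weight matrix of a conv module viewed as (k, k, cin, cout)
conv_w_array <- function(m) array(m$W, dim = c(m$k, m$k, m$cin, m$cout))

oracle_conv <- function(m, x) {
  d <- dim(x); k <- m$k; s <- m$s; p <- m$p
  Wa <- conv_w_array(m)
  oh <- (d[1] + 2 * p - k) %/% s + 1
  ow <- (d[2] + 2 * p - k) %/% s + 1
  y <- array(0, dim = c(oh, ow, m$cout))
  for (co in seq_len(m$cout)) {
    for (ox in seq_len(ow)) for (oy in seq_len(oh)) {
      acc <- if (is.null(m$b)) 0 else m$b[co]
      for (ci in seq_len(d[3])) for (kx in seq_len(k)) for (ky in seq_len(k)) {
        iy <- (oy - 1) * s - p + ky
        ix <- (ox - 1) * s - p + kx
        if (iy >= 1 && iy <= d[1] && ix >= 1 && ix <= d[2])
          acc <- acc + x[iy, ix, ci] * Wa[ky, kx, ci, co]
      }
      y[oy, ox, co] <- acc
    }
  }
  o_act(y, m$act)
}

oracle_dwconv <- function(m, x) {
  d <- dim(x); k <- m$k; s <- m$s; p <- m$p
  oh <- (d[1] + 2 * p - k) %/% s + 1
  ow <- (d[2] + 2 * p - k) %/% s + 1
  y <- array(0, dim = c(oh, ow, d[3]))
  replicate_pad <- identical(m$pad_mode, 1L)
  for (ci in seq_len(d[3])) {
    for (ox in seq_len(ow)) for (oy in seq_len(oh)) {
      acc <- m$b[ci]
      for (kx in seq_len(k)) for (ky in seq_len(k)) {
        iy <- (oy - 1) * s - p + ky
        ix <- (ox - 1) * s - p + kx
        if (replicate_pad) {
          iy <- min(max(iy, 1), d[1]); ix <- min(max(ix, 1), d[2])
        }
        if (iy >= 1 && iy <= d[1] && ix >= 1 && ix <= d[2])
          acc <- acc + x[iy, ix, ci] * m$W[ky, kx, ci]
      }
      y[oy, ox, ci] <- acc
    }
  }
  o_act(y, m$act)
}

oracle_dsconv <- function(m, x) oracle_conv(m$pw, oracle_dwconv(m$dw, x))

oracle_avgpool3 <- function(x) {
  d <- dim(x)
  y <- array(0, dim = d)
  for (ci in seq_len(d[3])) for (ox in seq_len(d[2])) for (oy in seq_len(d[1])) {
    acc <- 0; cnt <- 0
    for (dx in -1:1) for (dy in -1:1) {
      iy <- oy + dy; ix <- ox + dx
      if (iy >= 1 && iy <= d[1] && ix >= 1 && ix <= d[2]) {
        acc <- acc + x[iy, ix, ci]; cnt <- cnt + 1
      }
    }
    y[oy, ox, ci] <- acc / cnt
  }
  y
}

oracle_layernorm <- function(m, x) {
  d <- dim(x)
  y <- array(0, dim = d)
  for (ox in seq_len(d[2])) for (oy in seq_len(d[1])) {
    v <- x[oy, ox, ]
    mu <- mean(v)
    sd2 <- mean((v - mu)^2)
    y[oy, ox, ] <- (v - mu) / sqrt(sd2 + m$eps) * m$gamma + m$beta
  }
  y
}

oracle_poolformer <- function(m, x) {
  t1 <- oracle_layernorm(m$ln1, x)
  y <- x + oracle_avgpool3(t1) - t1
  y + oracle_conv(m$fc2, oracle_conv(m$fc1, oracle_layernorm(m$ln2, y)))
}

oracle_adaptive_pool <- function(x, oh, ow = oh) {
  d <- dim(x)
  y <- array(0, dim = c(oh, ow, d[3]))
  for (ci in seq_len(d[3])) for (ox in seq_len(ow)) for (oy in seq_len(oh)) {
    y0 <- floor((oy - 1) * d[1] / oh) + 1
    y1 <- ceiling(oy * d[1] / oh)
    x0 <- floor((ox - 1) * d[2] / ow) + 1
    x1 <- ceiling(ox * d[2] / ow)
    y[oy, ox, ci] <- mean(x[y0:y1, x0:x1, ci])
  }
  y
}

oracle_bilinear <- function(x, oh, ow = oh) {
  d <- dim(x)
  y <- array(0, dim = c(oh, ow, d[3]))
  coeff <- function(o, n_in, n_out) {
    src <- (o - 0.5) * n_in / n_out - 0.5
    src <- min(max(src, 0), n_in - 1)
    i0 <- floor(src)
    list(i0 = i0 + 1, i1 = min(i0 + 1, n_in - 1) + 1, w1 = src - i0)
  }
  for (ox in seq_len(ow)) {
    cx <- coeff(ox, d[2], ow)
    for (oy in seq_len(oh)) {
      cy <- coeff(oy, d[1], oh)
      for (ci in seq_len(d[3])) {
        y[oy, ox, ci] <-
          (1 - cy$w1) * ((1 - cx$w1) * x[cy$i0, cx$i0, ci] + cx$w1 * x[cy$i0, cx$i1, ci]) +
          cy$w1 * ((1 - cx$w1) * x[cy$i1, cx$i0, ci] + cx$w1 * x[cy$i1, cx$i1, ci])
      }
    }
  }
  y
}

oracle_efe <- function(m, x) {
  edge <- x - oracle_avgpool3(x)
  x + 1 / (1 + exp(-oracle_dsconv(m$ds, edge)))
}

oracle_edge_branch <- function(m, x) {
  d <- dim(x)
  r <- min(m$r, d[1], d[2])
  y <- oracle_adaptive_pool(x, r)
  y <- oracle_conv(m$reduce, y)
  y <- oracle_dsconv(m$ds, y)
  y <- oracle_efe(m$efe, y)
  oracle_bilinear(y, d[1], d[2])
}

oracle_cwg <- function(m, x) {
  d <- dim(x)
  g <- array(0, dim = c(1, 1, d[3]))
  for (ci in seq_len(d[3])) g[1, 1, ci] <- mean(x[, , ci])
  z <- oracle_conv(m$fc2, oracle_conv(m$fc1, g))
  1 / (1 + exp(-as.numeric(z)))
}

oracle_dmae <- function(m, x) {
  d <- dim(x)
  w <- oracle_cwg(m$cwg, x)
  parts <- list(w[1] * oracle_dsconv(m$local, x))
  for (i in seq_along(m$branches)) {
    parts[[i + 1]] <- w[i + 1] * oracle_edge_branch(m$branches[[i]], x)
  }
  z <- array(unlist(parts), dim = c(d[1], d[2], sum(sapply(parts, function(p) dim(p)[3]))))
  oracle_conv(m$fuse, z)
}

## ---- independent detection-metric reference ----------------------------

# Threshold-sweep AP: for every distinct confidence cutoff, re-run greedy
# matching from scratch and record one PR point; integrate the envelope.
reference_ap_envelope <- function(dets, gts, iou_thr) {
  n_gt <- nrow(gts)
  cuts <- sort(unique(dets$conf), decreasing = TRUE)
  pts <- data.frame(r = 0, p = 1)
  for (ct in cuts) {
    sub <- dets[dets$conf >= ct, , drop = FALSE]
    sub <- sub[order(sub$conf, decreasing = TRUE), , drop = FALSE]
    used <- logical(n_gt)
    tp <- 0
    for (i in seq_len(nrow(sub))) {
      best <- 0; bj <- 0
      for (j in seq_len(n_gt)) {
        if (used[j]) next
        iou <- ref_iou_cxcywh(as.numeric(sub[i, c("cx", "cy", "w", "h")]),
                              as.numeric(gts[j, c("cx", "cy", "w", "h")]))
        if (iou > best) { best <- iou; bj <- j }
      }
      if (bj > 0 && best >= iou_thr) { used[bj] <- TRUE; tp <- tp + 1 }
    }
    pts <- rbind(pts, data.frame(r = tp / n_gt, p = tp / nrow(sub)))
  }
  pts <- pts[-1, , drop = FALSE]
  ap <- 0
  r_prev <- 0
  for (i in seq_len(nrow(pts))) {
    p_max <- max(pts$p[pts$r >= pts$r[i]])
    ap <- ap + (pts$r[i] - r_prev) * p_max
    r_prev <- pts$r[i]
  }
  ap
}

ref_iou_cxcywh <- function(a, b) {
  ax1 <- a[1] - a[3] / 2; ay1 <- a[2] - a[4] / 2
  ax2 <- a[1] + a[3] / 2; ay2 <- a[2] + a[4] / 2
  bx1 <- b[1] - b[3] / 2; by1 <- b[2] - b[4] / 2
  bx2 <- b[1] + b[3] / 2; by2 <- b[2] + b[4] / 2
  iw <- max(0, min(ax2, bx2) - max(ax1, bx1))
  ih <- max(0, min(ay2, by2) - max(ay1, by1))
  inter <- iw * ih
  un <- (ax2 - ax1) * (ay2 - ay1) + (bx2 - bx1) * (by2 - by1) - inter
  if (un > 0) inter / un else 0
}

## ---- generic module checks ---------------------------------------------

# Finite-difference check of a module's backward pass: the scalar probe is
# sum(forward(x) * R) for a fixed random R.
grad_check_module <- function(m, x, n_input = 5, n_param = 5, eps = 1e-5,
                              tol = 1e-3, seed = 1) {
  set.seed(seed)
  y0 <- m$forward(x)
  R <- array(rnorm(length(y0)), dim = dim(y0))
  loss <- function() sum(m$forward(x) * R)
  pdayolo:::mod_zero_grad(m)
  m$forward(x)
  dx <- m$backward(R)
  ok <- TRUE
  for (i in sample(length(x), min(n_input, length(x)))) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g_num <- (sum(m$forward(xp) * R) - sum(m$forward(xm) * R)) / (2 * eps)
    rel <- abs(dx[i] - g_num) / max(1e-6, abs(dx[i]) + abs(g_num))
    if (rel > tol) ok <- FALSE
  }
  leaves <- pdayolo:::mod_leaves(m)
  leaves <- leaves[vapply(leaves, function(l) length(l$param_names) > 0, logical(1))]
  if (length(leaves) > 0 && n_param > 0) {
    for (rep in seq_len(n_param)) {
      leaf <- leaves[[sample.int(length(leaves), 1)]]
      p <- leaf$param_names[sample.int(length(leaf$param_names), 1)]
      i <- sample(length(leaf[[p]]), 1)
      g_ana <- leaf$grad[[p]][i]
      orig <- leaf[[p]][i]
      leaf[[p]][i] <- orig + eps; lp <- loss()
      leaf[[p]][i] <- orig - eps; lm <- loss()
      leaf[[p]][i] <- orig
      g_num <- (lp - lm) / (2 * eps)
      rel <- abs(g_ana - g_num) / max(1e-6, abs(g_ana) + abs(g_num))
      if (rel > tol) ok <- FALSE
    }
  }
  ok
}

zero_conv <- function(m) { m$W[] <- 0; if (!is.null(m$b)) m$b[] <- 0; invisible(m) }
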