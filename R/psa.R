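# C2PSA: the partial self-attention block at the deepest backbone stage of
# YOLO11 (kept unchanged in every variant). A 1x1 convolution splits the map
# into a pass-through half and an attention half; the attention half runs
# through PSA blocks (position-sensitive multi-head attention with a
# depthwise positional convolution, then a pointwise FFN, both residual).

new_psa_attention <- function(dim, num_heads, attn_ratio = 0.5) {
  m <- new_module_env("psa_attention")
  m$dim <- as.integer(dim); m$nh <- as.integer(num_heads)
  m$hd <- as.integer(dim %/% num_heads)
  m$kd <- as.integer(round(m$hd * attn_ratio))
  h <- dim + m$kd * m$nh * 2L
  m$qkv <- new_conv(dim, h, k = 1L, act = "none")
  m$proj <- new_conv(dim, dim, k = 1L, act = "none")
  m$pe <- new_dwconv(dim, k = 3L, s = 1L, act = "none")
  m$children <- list(m$qkv, m$proj, m$pe)
  m$forward <- function(x) {
    d <- fm_dims(x)
    n <- d[1] * d[2]
    qkv <- m$qkv$forward(x)
    Qf <- matrix(qkv[, , seq_len(m$kd * m$nh)], n, m$kd * m$nh)
    Kf <- matrix(qkv[, , m$kd * m$nh + seq_len(m$kd * m$nh)], n, m$kd * m$nh)
    Vf <- matrix(qkv[, , 2L * m$kd * m$nh + seq_len(m$dim)], n, m$dim)
    O <- matrix(0, n, m$dim)
    Alist <- vector("list", m$nh)
    for (hh in seq_len(m$nh)) {
      qi <- (hh - 1L) * m$kd + seq_len(m$kd)
      vi <- (hh - 1L) * m$hd + seq_len(m$hd)
      A <- softmax_rows(Qf[, qi, drop = FALSE] %*% t(Kf[, qi, drop = FALSE]) / sqrt(m$kd))
      Alist[[hh]] <- A
      O[, vi] <- A %*% Vf[, vi, drop = FALSE]
    }
    vmap <- array(Vf, dim = c(d[1], d[2], m$dim))
    pe <- m$pe$forward(vmap)
    m$cache <- list(d = d, Qf = Qf, Kf = Kf, Vf = Vf, A = Alist)
    m$proj$forward(array(O, dim = d) + pe)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    d <- cc$d; n <- d[1] * d[2]
    dsum <- m$proj$backward(dy)
    dVf_pe <- matrix(m$pe$backward(dsum), n, m$dim)
    dO <- matrix(dsum, n, m$dim)
    dQf <- matrix(0, n, m$kd * m$nh); dKf <- dQf
    dVf <- matrix(0, n, m$dim)
    for (hh in seq_len(m$nh)) {
      qi <- (hh - 1L) * m$kd + seq_len(m$kd)
      vi <- (hh - 1L) * m$hd + seq_len(m$hd)
      A <- cc$A[[hh]]
      dOh <- dO[, vi, drop = FALSE]
      dA <- dOh %*% t(cc$Vf[, vi, drop = FALSE])
      dVf[, vi] <- crossprod(A, dOh)
      dZ <- softmax_rows_grad(dA, A) / sqrt(m$kd)
      dQf[, qi] <- dZ %*% cc$Kf[, qi, drop = FALSE]
      dKf[, qi] <- crossprod(dZ, cc$Qf[, qi, drop = FALSE])
    }
    dVf <- dVf + dVf_pe
    dqkv <- array(c(dQf, dKf, dVf), dim = c(d[1], d[2], 2L * m$kd * m$nh + m$dim))
    m$qkv$backward(dqkv)
  }
  m$flops <- function(h, w) {
    f <- m$qkv$flops(h, w)$flops + m$proj$flops(h, w)$flops + m$pe$flops(h, w)$flops
    list(flops = f, h = h, w = w)
  }
  m
}

new_psa_block <- function(c, num_heads) {
  m <- new_module_env("psa_block")
  m$attn <- new_psa_attention(c, num_heads)
  m$ffn1 <- new_conv(c, 2L * c, k = 1L)
  m$ffn2 <- new_conv(2L * c, c, k = 1L, act = "none")
  m$children <- list(m$attn, m$ffn1, m$ffn2)
  m$forward <- function(x) {
    y <- x + m$attn$forward(x)
    y + m$ffn2$forward(m$ffn1$forward(y))
  }
  m$backward <- function(dy) {
    dyy <- dy + m$ffn1$backward(m$ffn2$backward(dy))
    dyy + m$attn$backward(dyy)
  }
  m$flops <- function(h, w) {
    f <- m$attn$flops(h, w)$flops + m$ffn1$flops(h, w)$flops + m$ffn2$flops(h, w)$flops
    list(flops = f, h = h, w = w)
  }
  m
}

new_c2psa <- function(c, n = 1L) {
  m <- new_module_env("c2psa")
  ch <- c %/% 2L
  m$cv1 <- new_conv(c, 2L * ch, k = 1L)
  m$cv2 <- new_conv(2L * ch, c, k = 1L)
  m$blocks <- lapply(seq_len(n), function(i) new_psa_block(ch, max(1L, ch %/% 64L)))
  m$children <- c(list(m$cv1, m$cv2), m$blocks)
  m$ch <- ch; m$cin <- c; m$cout <- c
  m$forward <- function(x) {
    y <- m$cv1$forward(x)
    a <- y[, , seq_len(m$ch), drop = FALSE]
    b <- y[, , m$ch + seq_len(m$ch), drop = FALSE]
    for (blk in m$blocks) b <- blk$forward(b)
    d <- dim(a)
    m$cv2$forward(array(c(a, b), dim = c(d[1], d[2], 2L * m$ch)))
  }
  m$backward <- function(dy) {
    dz <- m$cv2$backward(dy)
    da <- dz[, , seq_len(m$ch), drop = FALSE]
    db <- dz[, , m$ch + seq_len(m$ch), drop = FALSE]
    for (blk in rev(m$blocks)) db <- blk$backward(db)
    m$cv1$backward(array(c(da, db), dim = dim(dz)))
  }
  m$flops <- function(h, w) {
    f <- m$cv1$flops(h, w)$flops + m$cv2$flops(h, w)$flops
    for (blk in m$blocks) f <- f + blk$flops(h, w)$flops
    list(flops = f, h = h, w = w)
  }
  m
}
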