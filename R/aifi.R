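# Attention-based Intra-scale Feature Interaction (AIFI).
#
# The deepest backbone map (h x w x d) is flattened into h*w tokens; a fixed
# 2D sinusoidal positional embedding is added to the query/key inputs (values
# are left untouched); multi-head scaled dot-product self-attention, a
# residual connection and channel layer normalization follow, then a
# two-layer MLP (expand, then project back) with a second residual +
# normalization (post-norm order). The result is reshaped back to h x w x d.

#' 2D sinusoidal positional embedding
#'
#' Deterministic embedding for an `h x w` token grid. Each token's vector is
#' built from four quarters: sin and cos of the x position and sin and cos of
#' the y position at `embed_dim / 4` geometric frequencies, so every token has
#' squared norm `embed_dim / 2`.
#'
#' @param h,w grid height and width (tokens are enumerated row-major with x
#'   fastest, matching the column-major flattening of an `(h, w, c)` array
#'   transposed to tokens).
#' @param embed_dim embedding width; must be divisible by 4.
#' @param temperature frequency base (default 10000).
#' @return `h*w x embed_dim` matrix; token `t` corresponds to grid position
#'   `(y = (t-1) %% h, x = (t-1) %/% h)`.
#' @export
build_2d_sincos_pos_embed <- function(h, w, embed_dim, temperature = 10000) {
  if (embed_dim %% 4 != 0) stop("embed_dim must be divisible by 4")
  pos_dim <- embed_dim %/% 4L
  omega <- 1 / temperature^((seq_len(pos_dim) - 1) / pos_dim)
  # token order follows the (h, w) array flattening: y fastest
  grid_y <- rep(seq_len(h) - 1, times = w)
  grid_x <- rep(seq_len(w) - 1, each = h)
  out_x <- outer(grid_x, omega)
  out_y <- outer(grid_y, omega)
  cbind(sin(out_x), cos(out_x), sin(out_y), cos(out_y))
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with the softmax taken per query row; each
#' attention row sums to one.
#'
#' @param Q,K,V token matrices (`n_q x d`, `n_kv x d`, `n_kv x d_v`).
#' @param d_k scaling dimension; defaults to `ncol(K)`.
#' @param return_weights also return the attention matrix.
#' @return the `n_q x d_v` output matrix, or a list with `output` and
#'   `weights` when `return_weights = TRUE`.
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K), return_weights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  A <- softmax_rows(Q %*% t(K) / sqrt(d_k))
  out <- A %*% V
  if (return_weights) list(output = out, weights = A) else out
}

## ---- multi-head self-attention (tokens) --------------------------------

new_mhsa <- function(d, heads = 8L) {
  stopifnot(d %% heads == 0)
  m <- new_module_env("mhsa")
  m$d <- as.integer(d); m$heads <- as.integer(heads)
  m$hd <- as.integer(d %/% heads)
  for (nm in c("Wq", "Wk", "Wv", "Wo")) m[[nm]] <- matrix(he_uniform(d, d * d), d, d)
  for (nm in c("bq", "bk", "bv", "bo")) m[[nm]] <- numeric(d)
  m$param_names <- c("Wq", "Wk", "Wv", "Wo", "bq", "bk", "bv", "bo")
  m$forward <- function(x_tok, pos = NULL) {
    qk_in <- if (is.null(pos)) x_tok else x_tok + pos
    Q <- sweep(qk_in %*% m$Wq, 2L, m$bq, "+")
    K <- sweep(qk_in %*% m$Wk, 2L, m$bk, "+")
    V <- sweep(x_tok %*% m$Wv, 2L, m$bv, "+")
    n <- nrow(x_tok)
    O <- matrix(0, n, m$d)
    Alist <- vector("list", m$heads)
    for (hh in seq_len(m$heads)) {
      idx <- (hh - 1L) * m$hd + seq_len(m$hd)
      A <- softmax_rows(Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(m$hd))
      Alist[[hh]] <- A
      O[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    m$cache <- list(qk_in = qk_in, x = x_tok, Q = Q, K = K, V = V,
                    A = Alist, O = O)
    sweep(O %*% m$Wo, 2L, m$bo, "+")
  }
  m$backward <- function(dy) {
    cc <- m$cache
    m$grad$Wo <- m$grad$Wo + crossprod(cc$O, dy)
    m$grad$bo <- m$grad$bo + colSums(dy)
    dO <- dy %*% t(m$Wo)
    dQ <- matrix(0, nrow(dy), m$d); dK <- dQ; dV <- dQ
    for (hh in seq_len(m$heads)) {
      idx <- (hh - 1L) * m$hd + seq_len(m$hd)
      A <- cc$A[[hh]]
      dOh <- dO[, idx, drop = FALSE]
      dA <- dOh %*% t(cc$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(A, dOh)
      dZ <- softmax_rows_grad(dA, A) / sqrt(m$hd)
      dQ[, idx] <- dZ %*% cc$K[, idx, drop = FALSE]
      dK[, idx] <- crossprod(dZ, cc$Q[, idx, drop = FALSE])
    }
    m$grad$Wq <- m$grad$Wq + crossprod(cc$qk_in, dQ)
    m$grad$Wk <- m$grad$Wk + crossprod(cc$qk_in, dK)
    m$grad$Wv <- m$grad$Wv + crossprod(cc$x, dV)
    m$grad$bq <- m$grad$bq + colSums(dQ)
    m$grad$bk <- m$grad$bk + colSums(dK)
    m$grad$bv <- m$grad$bv + colSums(dV)
    # positional embedding is a constant; its share of the q/k path is dropped
    dQ %*% t(m$Wq) + dK %*% t(m$Wk) + dV %*% t(m$Wv)
  }
  m$flops_tokens <- function(n) 2 * n * m$d * m$d * 4
  m
}

## ---- AIFI block --------------------------------------------------------

#' AIFI configuration
#'
#' @param embed_dim channel count of the deepest backbone map (tokens'
#'   width); must be divisible by 4 and by `heads`.
#' @param heads attention head count.
#' @param hidden MLP hidden width.
#' @param temperature positional-embedding frequency base.
#' @return a `pda_aifi_config` list.
#' @export
aifi_config <- function(embed_dim = 256L, heads = 8L, hidden = 512L,
                        temperature = 10000) {
  stopifnot(embed_dim %% 4 == 0, embed_dim %% heads == 0, hidden >= 1)
  structure(list(embed_dim = as.integer(embed_dim), heads = as.integer(heads),
                 hidden = as.integer(hidden), temperature = temperature),
            class = "pda_aifi_config")
}

new_aifi <- function(cfg) {
  m <- new_module_env("aifi")
  d <- cfg$embed_dim
  m$cfg <- cfg
  m$attn <- new_mhsa(d, cfg$heads)
  m$ln1 <- new_layernorm(d)
  m$ln2 <- new_layernorm(d)
  m$fc1 <- new_conv(d, cfg$hidden, k = 1L, act = "gelu")
  m$fc2 <- new_conv(cfg$hidden, d, k = 1L, act = "none")
  m$children <- list(m$attn, m$ln1, m$ln2, m$fc1, m$fc2)
  m$cin <- d; m$cout <- d
  m$use_pos <- TRUE
  m$forward <- function(x) {
    dd <- fm_dims(x)
    if (dd[3] != m$cin) stop("aifi_forward: channels (", dd[3],
                             ") do not match embed_dim (", m$cin, ")")
    n <- dd[1] * dd[2]
    xt <- matrix(x, n, dd[3])
    pos <- if (m$use_pos)
      build_2d_sincos_pos_embed(dd[1], dd[2], m$cin, m$cfg$temperature) else NULL
    a <- m$attn$forward(xt, pos)
    y1 <- m$ln1$forward(array(xt + a, dim = c(dd[1], dd[2], dd[3])))
    f <- m$fc2$forward(m$fc1$forward(y1))
    out <- m$ln2$forward(y1 + f)
    m$cache_d <- dd
    out
  }
  m$backward <- function(dy) {
    dd <- m$cache_d
    g <- m$ln2$backward(dy)
    dy1 <- g + m$fc1$backward(m$fc2$backward(g))
    dxa <- m$ln1$backward(dy1)
    dxt <- matrix(dxa, dd[1] * dd[2], dd[3])
    dxt2 <- dxt + m$attn$backward(dxt)
    array(dxt2, dim = dd)
  }
  m$flops <- function(h, w) {
    n <- h * w
    f <- m$attn$flops_tokens(n) + m$fc1$flops(h, w)$flops + m$fc2$flops(h, w)$flops
    list(flops = f, h = h, w = w)
  }
  m
}

#' Attention-based intra-scale feature interaction
#'
#' Applies the AIFI transform to a feature map whose channel count equals
#' `cfg$embed_dim`. Output shape equals input shape. Deterministic given the
#' module parameters (no dropout).
#'
#' @param x feature map array `dim c(h, w, embed_dim)`.
#' @param cfg an [aifi_config()].
#' @param module optional prebuilt AIFI module (`new_aifi_block()`).
#' @param use_pos set `FALSE` to disable the positional embedding (the block
#'   then becomes equivariant to spatial permutations of the tokens).
#' @return feature map of the same shape as `x`.
#' @export
aifi_forward <- function(x, cfg = NULL, module = NULL, use_pos = TRUE) {
  if (is.null(module)) {
    if (is.null(cfg)) cfg <- aifi_config(embed_dim = fm_dims(x)[3])
    module <- new_aifi(cfg)
  }
  old <- module$use_pos
  module$use_pos <- use_pos
  on.exit(module$use_pos <- old)
  module$forward(x)
}

#' @rdname aifi_forward
#' @export
new_aifi_block <- function(cfg) new_aifi(cfg)
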