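# Baseline YOLO11 building blocks (Bottleneck, C3k, C3k2, SPPF) and their
# PoolFormer-modified counterparts (PoolFormer block, PF_C3k, PF_C3k2).
# The C3k2 block follows the cross-stage partial design: a 1x1 convolution
# produces 2*c hidden channels split into two halves, the second half runs
# through `repeat_n` inner blocks (C3k when mode_flag is TRUE, Bottleneck when
# FALSE; in the PF variant PF_C3k / PoolFormer respectively), and all pieces
# are concatenated and fused by a final 1x1 convolution.

#' Block configuration
#'
#' Describes one convolutional building block: channel counts, kernel,
#' stride, the inner-block repeat count, the TRUE/FALSE routing flag of the
#' C3k2 family, and the MLP expansion ratio used by PoolFormer blocks.
#'
#' @param in_channels,out_channels input and output channel counts.
#' @param kernel odd spatial kernel size.
#' @param stride positive integer stride.
#' @param repeat_n number of inner blocks (the network uses 1 throughout).
#' @param mode_flag logical; TRUE routes through C3k (or PF_C3k), FALSE
#'   through Bottleneck (or PoolFormer).
#' @param mlp_expansion hidden-width multiplier of the PoolFormer MLP.
#' @param expansion hidden-channel ratio of the split path (c = out * expansion).
#' @return a `pda_block_config` list.
#' @export
block_config <- function(in_channels, out_channels, kernel = 3L, stride = 1L,
                         repeat_n = 1L, mode_flag = FALSE, mlp_expansion = 4,
                         expansion = 0.5) {
  stopifnot(in_channels >= 1, out_channels >= 1, kernel %% 2 == 1,
            stride >= 1, repeat_n >= 1, mlp_expansion > 0, expansion > 0)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 repeat_n = as.integer(repeat_n), mode_flag = isTRUE(mode_flag),
                 mlp_expansion = mlp_expansion, expansion = expansion),
            class = "pda_block_config")
}

## ---- Bottleneck and C3k ------------------------------------------------

new_bottleneck <- function(cin, cout, shortcut = TRUE, e = 0.5,
                           k1 = 3L, k2 = 3L) {
  m <- new_module_env("bottleneck")
  ch <- max(1L, as.integer(round(cout * e)))
  m$cv1 <- new_conv(cin, ch, k = k1)
  m$cv2 <- new_conv(ch, cout, k = k2)
  m$children <- list(m$cv1, m$cv2)
  m$add <- shortcut && cin == cout
  m$cin <- cin; m$cout <- cout
  m$forward <- function(x) {
    y <- m$cv2$forward(m$cv1$forward(x))
    if (m$add) y + x else y
  }
  m$backward <- function(dy) {
    dx <- m$cv1$backward(m$cv2$backward(dy))
    if (m$add) dx + dy else dx
  }
  m$flops <- function(h, w) {
    f1 <- m$cv1$flops(h, w); f2 <- m$cv2$flops(f1$h, f1$w)
    list(flops = f1$flops + f2$flops, h = f2$h, w = f2$w)
  }
  m
}

# PoolFormer block: post-LN metaformer with an average-pooling token mixer.
# stage 1: y = x + (avgpool3(LN1(x)) - LN1(x));  stage 2: out = y + MLP(LN2(y)).
new_poolformer <- function(c, mlp_expansion = 4) {
  m <- new_module_env("poolformer")
  hidden <- max(1L, as.integer(round(c * mlp_expansion)))
  m$ln1 <- new_layernorm(c)
  m$ln2 <- new_layernorm(c)
  m$fc1 <- new_conv(c, hidden, k = 1L, act = "gelu")
  m$fc2 <- new_conv(hidden, c, k = 1L, act = "none")
  m$children <- list(m$ln1, m$ln2, m$fc1, m$fc2)
  m$cin <- c; m$cout <- c
  m$forward <- function(x) {
    t1 <- m$ln1$forward(x)
    y <- x + avgpool3_valid(t1) - t1
    out <- y + m$fc2$forward(m$fc1$forward(m$ln2$forward(y)))
    m$cache_y <- y
    out
  }
  m$backward <- function(dy) {
    dmlp <- m$ln2$backward(m$fc1$backward(m$fc2$backward(dy)))
    dyy <- dy + dmlp
    dt1 <- avgpool3_valid_grad(dyy) - dyy
    dyy + m$ln1$backward(dt1)
  }
  m$flops <- function(h, w) {
    f1 <- m$fc1$flops(h, w); f2 <- m$fc2$flops(h, w)
    list(flops = f1$flops + f2$flops, h = h, w = w)
  }
  m
}

# C3k: cross-stage block with two parallel 1x1 reductions, n full-width
# 3x3 Bottlenecks on one path, concatenation, 1x1 fusion. `inner` swaps the
# Bottlenecks for PoolFormer blocks in the PF variant.
new_c3k <- function(cin, cout, n = 2L, e = 0.5, inner = c("bottleneck", "poolformer"),
                    mlp_expansion = 4) {
  inner <- match.arg(inner)
  m <- new_module_env(if (inner == "bottleneck") "c3k" else "pf_c3k")
  ch <- max(1L, as.integer(round(cout * e)))
  m$cv1 <- new_conv(cin, ch, k = 1L)
  m$cv2 <- new_conv(cin, ch, k = 1L)
  m$cv3 <- new_conv(2L * ch, cout, k = 1L)
  m$blocks <- lapply(seq_len(n), function(i) {
    if (inner == "bottleneck") new_bottleneck(ch, ch, shortcut = TRUE, e = 1.0)
    else new_poolformer(ch, mlp_expansion)
  })
  m$children <- c(list(m$cv1, m$cv2, m$cv3), m$blocks)
  m$ch <- ch; m$cin <- cin; m$cout <- cout
  m$forward <- function(x) {
    a <- m$cv1$forward(x)
    for (b in m$blocks) a <- b$forward(a)
    b2 <- m$cv2$forward(x)
    d <- dim(a)
    z <- array(c(a, b2), dim = c(d[1], d[2], 2L * m$ch))
    m$cache_d <- d
    m$cv3$forward(z)
  }
  m$backward <- function(dy) {
    dz <- m$cv3$backward(dy)
    d <- m$cache_d
    da <- dz[, , seq_len(m$ch), drop = FALSE]
    db <- dz[, , m$ch + seq_len(m$ch), drop = FALSE]
    for (b in rev(m$blocks)) da <- b$backward(da)
    m$cv1$backward(da) + m$cv2$backward(db)
  }
  m$flops <- function(h, w) {
    f <- m$cv1$flops(h, w)$flops + m$cv2$flops(h, w)$flops + m$cv3$flops(h, w)$flops
    for (b in m$blocks) f <- f + b$flops(h, w)$flops
    list(flops = f, h = h, w = w)
  }
  m
}

## ---- C3k2 family -------------------------------------------------------

# variant "baseline": inner = C3k (mode_flag TRUE) / Bottleneck (FALSE)
# variant "pf":       inner = PF_C3k (TRUE) / PoolFormer (FALSE)
new_c3k2 <- function(cin, cout, n = 1L, mode_flag = FALSE, e = 0.5,
                     variant = c("baseline", "pf"), mlp_expansion = 4) {
  variant <- match.arg(variant)
  m <- new_module_env(if (variant == "baseline") "c3k2" else "pf_c3k2")
  ch <- max(1L, as.integer(round(cout * e)))
  m$cv1 <- new_conv(cin, 2L * ch, k = 1L)
  m$blocks <- lapply(seq_len(n), function(i) {
    if (variant == "baseline") {
      if (mode_flag) new_c3k(ch, ch, n = 2L) else new_bottleneck(ch, ch, shortcut = TRUE, e = 0.5)
    } else {
      if (mode_flag) new_c3k(ch, ch, n = 2L, inner = "poolformer",
                             mlp_expansion = mlp_expansion)
      else new_poolformer(ch, mlp_expansion)
    }
  })
  m$cv2 <- new_conv((2L + n) * ch, cout, k = 1L)
  m$children <- c(list(m$cv1), m$blocks, list(m$cv2))
  m$ch <- ch; m$n <- as.integer(n); m$cin <- cin; m$cout <- cout
  m$mode_flag <- isTRUE(mode_flag)
  m$forward <- function(x) {
    y0 <- m$cv1$forward(x)
    d <- dim(y0)
    parts <- list(y0[, , seq_len(m$ch), drop = FALSE],
                  y0[, , m$ch + seq_len(m$ch), drop = FALSE])
    for (b in m$blocks) parts[[length(parts) + 1L]] <- b$forward(parts[[length(parts)]])
    z <- array(unlist(parts, use.names = FALSE),
               dim = c(d[1], d[2], (2L + m$n) * m$ch))
    m$cv2$forward(z)
  }
  m$backward <- function(dy) {
    dz <- m$cv2$backward(dy)
    np <- 2L + m$n
    dparts <- lapply(seq_len(np), function(i) {
      dz[, , (i - 1L) * m$ch + seq_len(m$ch), drop = FALSE]
    })
    # chain: parts[[i+1]] = block_i(parts[[i]]) for i >= 2
    for (i in rev(seq_len(m$n))) {
      dparts[[i + 1L]] <- dparts[[i + 1L]] + m$blocks[[i]]$backward(dparts[[i + 2L]])
    }
    dy0 <- array(c(dparts[[1L]], dparts[[2L]]),
                 dim = c(dim(dparts[[1L]])[1:2], 2L * m$ch))
    m$cv1$backward(dy0)
  }
  m$flops <- function(h, w) {
    f <- m$cv1$flops(h, w)$flops + m$cv2$flops(h, w)$flops
    for (b in m$blocks) f <- f + b$flops(h, w)$flops
    list(flops = f, h = h, w = w)
  }
  m
}

## ---- SPPF --------------------------------------------------------------

new_sppf <- function(cin, cout, k = 5L) {
  m <- new_module_env("sppf")
  ch <- cin %/% 2L
  m$cv1 <- new_conv(cin, ch, k = 1L)
  m$cv2 <- new_conv(4L * ch, cout, k = 1L)
  m$pools <- lapply(1:3, function(i) new_maxpool(k = k, s = 1L))
  m$children <- c(list(m$cv1, m$cv2), m$pools)
  m$ch <- ch; m$cin <- cin; m$cout <- cout
  m$forward <- function(x) {
    y0 <- m$cv1$forward(x)
    y1 <- m$pools[[1]]$forward(y0)
    y2 <- m$pools[[2]]$forward(y1)
    y3 <- m$pools[[3]]$forward(y2)
    d <- dim(y0)
    m$cv2$forward(array(c(y0, y1, y2, y3), dim = c(d[1], d[2], 4L * m$ch)))
  }
  m$backward <- function(dy) {
    dz <- m$cv2$backward(dy)
    ch <- m$ch
    d0 <- dz[, , seq_len(ch), drop = FALSE]
    d1 <- dz[, , ch + seq_len(ch), drop = FALSE]
    d2 <- dz[, , 2L * ch + seq_len(ch), drop = FALSE]
    d3 <- dz[, , 3L * ch + seq_len(ch), drop = FALSE]
    d2 <- d2 + m$pools[[3]]$backward(d3)
    d1 <- d1 + m$pools[[2]]$backward(d2)
    d0 <- d0 + m$pools[[1]]$backward(d1)
    m$cv1$backward(d0)
  }
  m$flops <- function(h, w) {
    list(flops = m$cv1$flops(h, w)$flops + m$cv2$flops(h, w)$flops, h = h, w = w)
  }
  m
}

## ---- exported functional surfaces --------------------------------------

#' Depthwise-separable convolution block
#'
#' Constructs a DSConv module (depthwise k x k convolution followed by a
#' pointwise 1 x 1 convolution) from a [block_config()], or applies one to a
#' feature map.
#'
#' @param cfg a [block_config()].
#' @param act activation after each stage (`"silu"`, `"gelu"`, `"none"`, ...).
#' @param act_out activation after the pointwise stage.
#' @return `new_dsconv_block()`: a module; `dsconv_forward()`: a feature map
#'   with `cfg$out_channels` channels and unchanged spatial size.
#' @export
new_dsconv_block <- function(cfg, act = "silu", act_out = act) {
  new_dsconv(cfg$in_channels, cfg$out_channels, k = cfg$kernel,
             act = act, act_out = act_out)
}

#' @rdname new_dsconv_block
#' @param x feature map array `dim c(h, w, c)`.
#' @param module a module built by the matching constructor; built fresh from
#'   `cfg` (with the current RNG state) when omitted.
#' @export
dsconv_forward <- function(x, cfg = NULL, module = NULL) {
  if (is.null(module)) module <- new_dsconv_block(cfg)
  if (fm_dims(x)[3] != module$cin)
    stop("dsconv_forward: input has ", fm_dims(x)[3], " channels, module expects ", module$cin)
  module$forward(x)
}

#' PoolFormer block
#'
#' Token-mixing block whose mixer is a 3 x 3 average pooling (valid-cell
#' divisor) minus the identity, preceded by channel-wise layer normalization
#' and followed by a two-layer pointwise MLP; both stages carry residual
#' connections. Requires `in_channels == out_channels`.
#'
#' @inheritParams new_dsconv_block
#' @return a module / the transformed feature map.
#' @export
new_poolformer_block <- function(cfg) {
  if (cfg$in_channels != cfg$out_channels)
    stop("poolformer block needs in_channels == out_channels for its residuals")
  new_poolformer(cfg$in_channels, cfg$mlp_expansion)
}

#' @rdname new_poolformer_block
#' @inheritParams dsconv_forward
#' @export
poolformer_forward <- function(x, cfg = NULL, module = NULL) {
  if (is.null(module)) module <- new_poolformer_block(cfg)
  if (fm_dims(x)[3] != module$cin)
    stop("poolformer_forward: channel mismatch")
  module$forward(x)
}

#' Baseline and PoolFormer C3k2 blocks
#'
#' `new_c3k2_block()` builds the baseline C3k2 (inner C3k when
#' `cfg$mode_flag`, Bottleneck otherwise); `new_pf_c3k2_block()` builds the
#' PF_C3k2 variant where the inner C3k becomes PF_C3k (its Bottlenecks
#' replaced by PoolFormer blocks) and the inner Bottleneck becomes a
#' PoolFormer block.
#'
#' @inheritParams new_dsconv_block
#' @return a module / the transformed feature map.
#' @export
new_c3k2_block <- function(cfg) {
  new_c3k2(cfg$in_channels, cfg$out_channels, n = cfg$repeat_n,
           mode_flag = cfg$mode_flag, e = cfg$expansion, variant = "baseline")
}

#' @rdname new_c3k2_block
#' @export
new_pf_c3k2_block <- function(cfg) {
  new_c3k2(cfg$in_channels, cfg$out_channels, n = cfg$repeat_n,
           mode_flag = cfg$mode_flag, e = cfg$expansion, variant = "pf",
           mlp_expansion = cfg$mlp_expansion)
}

#' @rdname new_c3k2_block
#' @inheritParams dsconv_forward
#' @export
baseline_c3k2_forward <- function(x, cfg = NULL, module = NULL) {
  if (is.null(module)) module <- new_c3k2_block(cfg)
  module$forward(x)
}

#' @rdname new_c3k2_block
#' @inheritParams dsconv_forward
#' @export
pf_c3k2_forward <- function(x, cfg = NULL, module = NULL) {
  if (is.null(module)) module <- new_pf_c3k2_block(cfg)
  module$forward(x)
}

#' Inner block types of a composite module
#'
#' Recursively lists the `type` labels of a module and its children, used to
#' verify which pathway (C3k vs Bottleneck vs PoolFormer) a configuration
#' instantiates.
#'
#' @param module a module object.
#' @return character vector of type labels.
#' @export
module_census <- function(module) {
  out <- module$type
  for (ch in module$children) out <- c(out, module_census(ch))
  out
}
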