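# Low-level neural modules. A module is an environment holding parameter
# arrays, their gradient accumulators, a forward closure (which caches what
# backward needs), a backward closure (which returns the input gradient and
# accumulates parameter gradients), and a flops closure used by the analytic
# complexity accountant. Feature maps are numeric arrays dim c(h, w, c).

fm_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("feature map must be an array with dim c(h, w, c)")
  d
}

#' Create a feature map array
#'
#' Convenience constructor for the height x width x channels arrays that all
#' block forward functions consume.
#'
#' @param values numeric vector (recycled) or array of values.
#' @param h,w,c height, width and channel count.
#' @return numeric array with `dim = c(h, w, c)`.
#' @export
feature_map <- function(values, h, w, c) {
  array(values, dim = c(h, w, c))
}

## ---- activations -------------------------------------------------------

act_fwd <- function(z, act) {
  switch(act,
    silu = z * stats::plogis(z),
    gelu = z * stats::pnorm(z),
    sigmoid = stats::plogis(z),
    relu = pmax(z, 0),
    none = z,
    stop("unknown activation: ", act)
  )
}

act_bwd <- function(dy, z, act) {
  switch(act,
    silu = { s <- stats::plogis(z); dy * (s + z * s * (1 - s)) },
    gelu = dy * (stats::pnorm(z) + z * stats::dnorm(z)),
    sigmoid = { s <- stats::plogis(z); dy * s * (1 - s) },
    relu = dy * (z > 0),
    none = dy,
    stop("unknown activation: ", act)
  )
}

## ---- parameter plumbing ------------------------------------------------

new_module_env <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$param_names <- character()
  m$children <- list()
  m$grad <- list()
  m$mom <- list()
  class(m) <- c(paste0("pda_", type), "pda_module")
  m
}

he_uniform <- function(fan_in, n) {
  bound <- sqrt(6 / max(fan_in, 1))
  runif(n, -bound, bound)
}

# All leaf modules (those owning parameters) in a module tree.
mod_leaves <- function(m) {
  if (length(m$children) == 0L) return(list(m))
  out <- list()
  if (length(m$param_names) > 0L) out <- list(m)
  for (ch in m$children) out <- c(out, mod_leaves(ch))
  out
}

mod_zero_grad <- function(m) {
  for (leaf in mod_leaves(m)) {
    for (p in leaf$param_names) {
      g <- leaf[[p]]
      g[] <- 0
      leaf$grad[[p]] <- g
    }
  }
  invisible(m)
}

mod_n_params <- function(m) {
  sum(vapply(mod_leaves(m), function(leaf) {
    sum(vapply(leaf$param_names, function(p) length(leaf[[p]]), numeric(1)))
  }, numeric(1)))
}

mod_param_sum <- function(m) {
  sum(vapply(mod_leaves(m), function(leaf) {
    sum(vapply(leaf$param_names, function(p) sum(leaf[[p]]), numeric(1)))
  }, numeric(1)))
}

mod_sgd_step <- function(m, lr, momentum = 0, weight_decay = 0) {
  for (leaf in mod_leaves(m)) {
    for (p in leaf$param_names) {
      g <- leaf$grad[[p]]
      if (is.null(g)) next
      if (weight_decay > 0) g <- g + weight_decay * leaf[[p]]
      if (momentum > 0) {
        v <- leaf$mom[[p]]
        if (is.null(v)) v <- g * 0
        v <- momentum * v + g
        leaf$mom[[p]] <- v
        g <- v
      }
      leaf[[p]] <- leaf[[p]] - lr * g
    }
  }
  invisible(m)
}

## ---- convolution -------------------------------------------------------

conv_out <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1L

# k x k convolution (+ bias + activation). The batch-norm of the reference
# blocks is kept in fused form: its affine part lives in W and b. Weight is
# stored as a (k*k*cin) x cout matrix whose rows flatten a (k, k, cin) patch.
new_conv <- function(cin, cout, k = 1L, s = 1L, act = "silu", bias = TRUE,
                     zero_init = FALSE) {
  m <- new_module_env("conv")
  m$cin <- cin; m$cout <- cout; m$k <- as.integer(k); m$s <- as.integer(s)
  m$p <- as.integer(k %/% 2); m$act <- act
  m$W <- matrix(if (zero_init) 0 else he_uniform(k * k * cin, k * k * cin * cout),
                k * k * cin, cout)
  m$param_names <- "W"
  if (bias) {
    m$b <- numeric(cout)
    m$param_names <- c("W", "b")
  }
  m$forward <- function(x) {
    d <- fm_dims(x)
    stopifnot(d[3] == m$cin)
    if (m$k == 1L && m$s == 1L) {
      cols <- matrix(x, d[1] * d[2], d[3])
      oh <- d[1]; ow <- d[2]
    } else {
      cols <- im2col_cpp(as.numeric(x), d[1], d[2], d[3], m$k, m$s, m$p)
      oh <- conv_out(d[1], m$k, m$s, m$p); ow <- conv_out(d[2], m$k, m$s, m$p)
    }
    z <- cols %*% m$W
    if (!is.null(m$b)) z <- sweep(z, 2L, m$b, "+")
    m$cache <- list(cols = cols, z = z, d = d, oh = oh, ow = ow)
    array(act_fwd(z, m$act), dim = c(oh, ow, m$cout))
  }
  m$backward <- function(dy) {
    cc <- m$cache
    dz <- act_bwd(matrix(dy, cc$oh * cc$ow, m$cout), cc$z, m$act)
    m$grad$W <- m$grad$W + crossprod(cc$cols, dz)
    if (!is.null(m$b)) m$grad$b <- m$grad$b + colSums(dz)
    dcols <- dz %*% t(m$W)
    if (m$k == 1L && m$s == 1L) {
      array(dcols, dim = cc$d)
    } else {
      array(col2im_cpp(dcols, cc$d[1], cc$d[2], cc$d[3], m$k, m$s, m$p), dim = cc$d)
    }
  }
  m$flops <- function(h, w) {
    oh <- conv_out(h, m$k, m$s, m$p); ow <- conv_out(w, m$k, m$s, m$p)
    list(flops = 2 * oh * ow * m$cout * m$k * m$k * m$cin, h = oh, w = ow)
  }
  m
}

# Depthwise k x k convolution (+ bias + activation); W has dim (k, k, c).
# pad = "zero" is the usual convolution border; pad = "replicate" clamps
# border indices so spatially constant maps stay exactly constant (used by
# the edge-aware DMAE stages).
new_dwconv <- function(c, k = 3L, s = 1L, act = "silu", pad = "zero") {
  m <- new_module_env("dwconv")
  m$c <- c; m$k <- as.integer(k); m$s <- as.integer(s)
  m$p <- as.integer(k %/% 2); m$act <- act
  m$pad_mode <- if (identical(pad, "replicate")) 1L else 0L
  m$W <- array(he_uniform(k * k, k * k * c), dim = c(k, k, c))
  m$b <- numeric(c)
  m$param_names <- c("W", "b")
  m$forward <- function(x) {
    d <- fm_dims(x)
    stopifnot(d[3] == m$c)
    oh <- conv_out(d[1], m$k, m$s, m$p); ow <- conv_out(d[2], m$k, m$s, m$p)
    z <- array(dwconv_fwd_cpp(as.numeric(x), d[1], d[2], d[3],
                              as.numeric(m$W), m$k, m$s, m$p, m$pad_mode),
               dim = c(oh, ow, m$c))
    z <- sweep(z, 3L, m$b, "+")
    m$cache <- list(x = x, z = z, d = d)
    act_fwd(z, m$act)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    dz <- act_bwd(dy, cc$z, m$act)
    bw <- dwconv_bwd_cpp(as.numeric(dz), as.numeric(cc$x), cc$d[1], cc$d[2],
                         cc$d[3], as.numeric(m$W), m$k, m$s, m$p, m$pad_mode)
    m$grad$W <- m$grad$W + array(bw$dW, dim = dim(m$W))
    m$grad$b <- m$grad$b + colSums(matrix(dz, ncol = m$c))
    array(bw$dx, dim = cc$d)
  }
  m$flops <- function(h, w) {
    oh <- conv_out(h, m$k, m$s, m$p); ow <- conv_out(w, m$k, m$s, m$p)
    list(flops = 2 * oh * ow * m$c * m$k * m$k, h = oh, w = ow)
  }
  m
}

# Depthwise-separable convolution: depthwise k x k then pointwise 1 x 1.
new_dsconv <- function(cin, cout, k = 3L, act = "silu", act_out = act,
                       pad = "zero") {
  m <- new_module_env("dsconv")
  m$dw <- new_dwconv(cin, k = k, s = 1L, act = act, pad = pad)
  m$pw <- new_conv(cin, cout, k = 1L, act = act_out)
  m$children <- list(m$dw, m$pw)
  m$cin <- cin; m$cout <- cout
  m$forward <- function(x) m$pw$forward(m$dw$forward(x))
  m$backward <- function(dy) m$dw$backward(m$pw$backward(dy))
  m$flops <- function(h, w) {
    f1 <- m$dw$flops(h, w); f2 <- m$pw$flops(f1$h, f1$w)
    list(flops = f1$flops + f2$flops, h = f2$h, w = f2$w)
  }
  m
}

## ---- parameterless spatial ops ----------------------------------------

avgpool3_valid <- function(x) {
  d <- fm_dims(x)
  array(avgpool3_valid_fwd_cpp(as.numeric(x), d[1], d[2], d[3]), dim = d)
}

avgpool3_valid_grad <- function(dy) {
  d <- fm_dims(dy)
  array(avgpool3_valid_bwd_cpp(as.numeric(dy), d[1], d[2], d[3]), dim = d)
}

adaptive_avgpool <- function(x, oh, ow = oh) {
  d <- fm_dims(x)
  array(adaptive_avgpool_fwd_cpp(as.numeric(x), d[1], d[2], d[3],
                                 as.integer(oh), as.integer(ow)),
        dim = c(oh, ow, d[3]))
}

adaptive_avgpool_grad <- function(dy, h, w) {
  d <- fm_dims(dy)
  array(adaptive_avgpool_bwd_cpp(as.numeric(dy), h, w, d[3], d[1], d[2]),
        dim = c(h, w, d[3]))
}

bilinear_resize <- function(x, oh, ow = oh) {
  d <- fm_dims(x)
  array(bilinear_fwd_cpp(as.numeric(x), d[1], d[2], d[3],
                         as.integer(oh), as.integer(ow)),
        dim = c(oh, ow, d[3]))
}

bilinear_resize_grad <- function(dy, h, w) {
  d <- fm_dims(dy)
  array(bilinear_bwd_cpp(as.numeric(dy), h, w, d[3], d[1], d[2]),
        dim = c(h, w, d[3]))
}

upsample2x_nearest <- function(x) {
  d <- fm_dims(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample2x_nearest_grad <- function(dy) {
  d <- fm_dims(dy)
  h <- d[1] %/% 2L; w <- d[2] %/% 2L
  oi <- seq(1L, d[1], by = 2L); oj <- seq(1L, d[2], by = 2L)
  dy[oi, oj, , drop = FALSE] + dy[oi + 1L, oj, , drop = FALSE] +
    dy[oi, oj + 1L, , drop = FALSE] + dy[oi + 1L, oj + 1L, , drop = FALSE]
}

new_maxpool <- function(k = 5L, s = 1L) {
  m <- new_module_env("maxpool")
  m$k <- as.integer(k); m$s <- as.integer(s); m$p <- as.integer(k %/% 2)
  m$forward <- function(x) {
    d <- fm_dims(x)
    r <- maxpool_fwd_cpp(as.numeric(x), d[1], d[2], d[3], m$k, m$s, m$p)
    oh <- conv_out(d[1], m$k, m$s, m$p); ow <- conv_out(d[2], m$k, m$s, m$p)
    m$cache <- list(argmax = r$argmax, n = prod(d), d = d)
    array(r$y, dim = c(oh, ow, d[3]))
  }
  m$backward <- function(dy) {
    cc <- m$cache
    array(maxpool_bwd_cpp(as.numeric(dy), cc$argmax, cc$n), dim = cc$d)
  }
  m$flops <- function(h, w) {
    list(flops = 0, h = conv_out(h, m$k, m$s, m$p), w = conv_out(w, m$k, m$s, m$p))
  }
  m
}

## ---- channel-wise layer normalization ----------------------------------

# Normalizes across channels independently at every spatial location.
new_layernorm <- function(c, eps = 1e-5) {
  m <- new_module_env("layernorm")
  m$c <- c; m$eps <- eps
  m$gamma <- rep(1, c); m$beta <- numeric(c)
  m$param_names <- c("gamma", "beta")
  m$forward <- function(x) {
    d <- fm_dims(x)
    X <- matrix(x, d[1] * d[2], d[3])
    mu <- rowMeans(X)
    xc <- X - mu
    inv <- 1 / sqrt(rowMeans(xc^2) + m$eps)
    xhat <- xc * inv
    m$cache <- list(xhat = xhat, inv = inv, d = d)
    array(sweep(sweep(xhat, 2L, m$gamma, "*"), 2L, m$beta, "+"), dim = d)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    dY <- matrix(dy, nrow(cc$xhat), m$c)
    m$grad$gamma <- m$grad$gamma + colSums(dY * cc$xhat)
    m$grad$beta <- m$grad$beta + colSums(dY)
    dxhat <- sweep(dY, 2L, m$gamma, "*")
    C <- m$c
    dx <- (cc$inv / C) * (C * dxhat - rowSums(dxhat) - cc$xhat * rowSums(dxhat * cc$xhat))
    array(dx, dim = cc$d)
  }
  m$flops <- function(h, w) list(flops = 0, h = h, w = w)
  m
}

## ---- softmax helpers ---------------------------------------------------

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

softmax_rows_grad <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}
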