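# Dynamic Multi-scale Aware Edge (DMAE) module.
#
# A local branch (3x3 DSConv at full resolution) runs in parallel with n
# edge-aware branches. Each edge-aware branch adaptively average-pools the
# input to r x r (r taken from feat_rls), reduces channels with a 1x1
# convolution, extracts features with a 3x3 DSConv, sharpens boundaries with
# the Edge Feature Enhancement (EFE) operator
#     F_edge = F_in - avgpool3x3(F_in)
#     F_out  = F_in + sigmoid(DSConv3x3(F_edge))
# and is resized back to the input resolution bilinearly. A Complexity-based
# Weight Generator (CWG) turns globally pooled features into one sigmoid
# weight per branch; weighted branch outputs are concatenated and fused by a
# final 1x1 convolution back to the input channel count.

#' DMAE configuration
#'
#' @param in_channels input (= output) channel count.
#' @param feat_rls strictly increasing target resolutions of the edge-aware
#'   branches (adaptive-pooling sizes).
#' @param reduction channel-reduction divisor of the branch 1x1 convolution.
#' @return a `pda_dmae_config` list with `n = length(feat_rls)`.
#' @export
dmae_config <- function(in_channels, feat_rls = c(3L, 6L, 9L, 12L), reduction = 3L) {
  feat_rls <- as.integer(feat_rls)
  if (length(feat_rls) < 1 || any(feat_rls < 1) || any(diff(feat_rls) <= 0))
    stop("feat_rls must be a strictly increasing vector of resolutions >= 1")
  stopifnot(in_channels >= 1, reduction >= 1)
  structure(list(in_channels = as.integer(in_channels), feat_rls = feat_rls,
                 n = length(feat_rls), reduction = as.integer(reduction),
                 out_channels = as.integer(in_channels)),
            class = "pda_dmae_config")
}

## ---- EFE ---------------------------------------------------------------

new_efe <- function(c) {
  m <- new_module_env("efe")
  m$ds <- new_dsconv(c, c, k = 3L, act = "none", act_out = "none",
                     pad = "replicate")
  m$children <- list(m$ds)
  m$cin <- c; m$cout <- c
  m$forward <- function(x) {
    edge <- x - avgpool3_valid(x)
    z <- m$ds$forward(edge)
    m$cache_z <- z
    x + stats::plogis(z)
  }
  m$backward <- function(dy) {
    s <- stats::plogis(m$cache_z)
    dedge <- m$ds$backward(dy * s * (1 - s))
    dy + dedge - avgpool3_valid_grad(dedge)
  }
  m$flops <- function(h, w) list(flops = m$ds$flops(h, w)$flops, h = h, w = w)
  m
}

#' Edge Feature Enhancement operator
#'
#' Computes `F_out = F_in + sigmoid(DSConv3x3(F_in - avgpool3x3(F_in)))`.
#' The 3 x 3 average pooling uses a valid-cell divisor, so a spatially
#' constant input yields an exactly zero edge map everywhere, including the
#' borders.
#'
#' @param x feature map array `dim c(h, w, c)`.
#' @param module an EFE module from `new_efe_block()`; built fresh (current
#'   RNG state) when omitted.
#' @param edge_only return the raw edge map `F_in - avgpool3x3(F_in)` instead.
#' @return feature map of the same shape as `x`.
#' @export
efe_forward <- function(x, module = NULL, edge_only = FALSE) {
  if (edge_only) return(x - avgpool3_valid(x))
  if (is.null(module)) module <- new_efe_block(fm_dims(x)[3])
  module$forward(x)
}

#' @rdname efe_forward
#' @param c channel count.
#' @export
new_efe_block <- function(c) new_efe(c)

## ---- edge-aware branch -------------------------------------------------

# `strict = TRUE` (the standalone op contract) rejects branch resolutions
# larger than the input map; inside the assembled detector the resolution is
# instead capped at the map size so the network stays valid at small input
# sizes (at 640x640 the cap never binds).
new_edge_branch <- function(cfg, r, strict = TRUE) {
  m <- new_module_env("edge_branch")
  cr <- max(1L, cfg$in_channels %/% cfg$reduction)
  m$reduce <- new_conv(cfg$in_channels, cr, k = 1L)
  m$ds <- new_dsconv(cr, cr, k = 3L, pad = "replicate")
  m$efe <- new_efe(cr)
  m$children <- list(m$reduce, m$ds, m$efe)
  m$r <- as.integer(r); m$cin <- cfg$in_channels; m$cout <- cr
  m$strict <- isTRUE(strict)
  m$forward <- function(x) {
    d <- fm_dims(x)
    if (m$strict && (m$r > d[1] || m$r > d[2]))
      stop("edge branch resolution ", m$r, " exceeds input spatial size ",
           d[1], "x", d[2])
    reff <- min(m$r, d[1], d[2])
    m$cache_d <- d
    m$cache_r <- reff
    y <- adaptive_avgpool(x, reff)
    y <- m$efe$forward(m$ds$forward(m$reduce$forward(y)))
    bilinear_resize(y, d[1], d[2])
  }
  m$backward <- function(dy) {
    d <- m$cache_d
    g <- bilinear_resize_grad(dy, m$cache_r, m$cache_r)
    g <- m$reduce$backward(m$ds$backward(m$efe$backward(g)))
    adaptive_avgpool_grad(g, d[1], d[2])
  }
  m$flops <- function(h, w) {
    reff <- min(m$r, h, w)
    f <- m$reduce$flops(reff, reff)$flops + m$ds$flops(reff, reff)$flops +
      m$efe$flops(reff, reff)$flops
    list(flops = f, h = h, w = w)
  }
  m
}

#' Edge-aware branch of the DMAE module
#'
#' Adaptive average pooling to r-by-r, 1x1 channel reduction, 3x3 DSConv,
#' EFE enhancement, then bilinear upsampling back to the input size.
#'
#' @param x feature map array.
#' @param r branch resolution; must be one of `cfg$feat_rls` and no larger
#'   than the input spatial size.
#' @param cfg a [dmae_config()].
#' @param module optional prebuilt branch module.
#' @return feature map `h x w x (in_channels / reduction)`.
#' @export
edge_branch_forward <- function(x, r, cfg = NULL, module = NULL) {
  if (is.null(module)) {
    if (!(r %in% cfg$feat_rls)) stop("r must be one of cfg$feat_rls")
    module <- new_edge_branch(cfg, r)
  }
  module$forward(x)
}

## ---- CWG ---------------------------------------------------------------

new_cwg <- function(cfg) {
  m <- new_module_env("cwg")
  ch <- max(4L, cfg$in_channels %/% 8L)
  m$fc1 <- new_conv(cfg$in_channels, ch, k = 1L, act = "relu")
  m$fc2 <- new_conv(ch, cfg$n + 1L, k = 1L, act = "none")
  m$children <- list(m$fc1, m$fc2)
  m$n <- cfg$n; m$cin <- cfg$in_channels
  m$forward <- function(x) {
    d <- fm_dims(x)
    m$cache_d <- d
    g <- adaptive_avgpool(x, 1L)
    z <- m$fc2$forward(m$fc1$forward(g))
    w <- stats::plogis(as.numeric(z))
    m$cache_w <- w
    w
  }
  m$backward <- function(dw) {
    w <- m$cache_w
    dz <- array(dw * w * (1 - w), dim = c(1L, 1L, m$n + 1L))
    g <- m$fc1$backward(m$fc2$backward(dz))
    adaptive_avgpool_grad(g, m$cache_d[1], m$cache_d[2])
  }
  m$flops <- function(h, w) {
    f <- m$fc1$flops(1L, 1L)$flops + m$fc2$flops(1L, 1L)$flops
    list(flops = f, h = h, w = w)
  }
  m
}

#' Complexity-based Weight Generator
#'
#' Global average pooling followed by a two-layer pointwise convolution stack
#' and an independent sigmoid per branch, yielding `n + 1` scalar weights in
#' (0, 1): one for the local branch and one per edge-aware branch.
#'
#' @param x feature map array.
#' @param cfg a [dmae_config()].
#' @param module optional prebuilt CWG module.
#' @return list with `w_local` (scalar) and `w_edge` (length-`n` vector).
#' @export
cwg_forward <- function(x, cfg = NULL, module = NULL) {
  if (is.null(module)) module <- new_cwg(cfg)
  w <- module$forward(x)
  list(w_local = w[1L], w_edge = w[-1L])
}

## ---- full DMAE ---------------------------------------------------------

new_dmae <- function(cfg) {
  m <- new_module_env("dmae")
  cr <- max(1L, cfg$in_channels %/% cfg$reduction)
  m$cfg <- cfg
  m$local <- new_dsconv(cfg$in_channels, cfg$in_channels, k = 3L,
                        pad = "replicate")
  m$branches <- lapply(cfg$feat_rls, function(r) new_edge_branch(cfg, r, strict = FALSE))
  m$cwg <- new_cwg(cfg)
  m$fuse <- new_conv(cfg$in_channels + cfg$n * cr, cfg$out_channels, k = 1L)
  m$children <- c(list(m$local, m$cwg, m$fuse), m$branches)
  m$cr <- cr; m$cin <- cfg$in_channels; m$cout <- cfg$out_channels
  m$forward <- function(x) {
    d <- fm_dims(x)
    if (d[3] != m$cin) stop("dmae_forward: input has ", d[3],
                            " channels, config expects ", m$cin)
    w <- m$cwg$forward(x)
    outs <- vector("list", m$cfg$n + 1L)
    outs[[1L]] <- m$local$forward(x)
    for (i in seq_len(m$cfg$n)) outs[[i + 1L]] <- m$branches[[i]]$forward(x)
    m$cache <- list(outs = outs, w = w, d = d)
    z <- array(c(w[1L] * outs[[1L]],
                 unlist(lapply(seq_len(m$cfg$n), function(i) w[i + 1L] * outs[[i + 1L]]),
                        use.names = FALSE)),
               dim = c(d[1], d[2], m$cin + m$cfg$n * m$cr))
    m$fuse$forward(z)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    dz <- m$fuse$backward(dy)
    w <- cc$w
    dw <- numeric(m$cfg$n + 1L)
    dloc <- dz[, , seq_len(m$cin), drop = FALSE]
    dw[1L] <- sum(dloc * cc$outs[[1L]])
    dx <- m$local$backward(w[1L] * dloc)
    off <- m$cin
    for (i in seq_len(m$cfg$n)) {
      dbi <- dz[, , off + seq_len(m$cr), drop = FALSE]
      off <- off + m$cr
      dw[i + 1L] <- sum(dbi * cc$outs[[i + 1L]])
      dx <- dx + m$branches[[i]]$backward(w[i + 1L] * dbi)
    }
    dx + m$cwg$backward(dw)
  }
  m$flops <- function(h, w) {
    f <- m$local$flops(h, w)$flops + m$cwg$flops(h, w)$flops +
      m$fuse$flops(h, w)$flops
    for (b in m$branches) f <- f + b$flops(h, w)$flops
    list(flops = f, h = h, w = w)
  }
  m
}

#' Dynamic Multi-scale Aware Edge module
#'
#' Applies the full DMAE transform: CWG branch weights, weighted local and
#' edge-aware branch outputs, channel concatenation, and 1x1 fusion back to
#' the input channel count. Spatial size and channel count are preserved, so
#' the module can be inserted into the neck without rewiring.
#'
#' @param x feature map array with `cfg$in_channels` channels.
#' @param cfg a [dmae_config()].
#' @param module optional prebuilt DMAE module (`new_dmae_block()`).
#' @return feature map of the same shape as `x`.
#' @export
dmae_forward <- function(x, cfg = NULL, module = NULL) {
  if (is.null(module)) module <- new_dmae(cfg)
  module$forward(x)
}

#' @rdname dmae_forward
#' @export
new_dmae_block <- function(cfg) new_dmae(cfg)
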