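# Detector assembly at YOLO11n scale (width 0.25, depth 0.50). The layer
# graph follows the standard backbone / PAN-neck / three-scale head wiring;
# the three optional modifications are: every C3k2 -> PF_C3k2, SPPF -> AIFI,
# and one channel-preserving DMAE at each neck output feeding the head.

#' Model variant switches
#'
#' The three architectural modifications; all eight combinations are
#' constructible. `(FALSE, FALSE, FALSE)` is the unmodified baseline,
#' `(TRUE, TRUE, TRUE)` the full detector.
#'
#' @param pf_c3k2 replace all C3k2 blocks with PF_C3k2.
#' @param dmae insert DMAE modules at the three neck outputs.
#' @param aifi replace SPPF with AIFI.
#' @return a `pda_variant` list.
#' @export
model_variant <- function(pf_c3k2 = FALSE, dmae = FALSE, aifi = FALSE) {
  structure(list(pf_c3k2 = isTRUE(pf_c3k2), dmae = isTRUE(dmae),
                 aifi = isTRUE(aifi)), class = "pda_variant")
}

#' @rdname model_variant
#' @param spec comma-separated subset of `"pf"`, `"dmae"`, `"aifi"` (empty
#'   string or `"baseline"` for the baseline).
#' @export
parse_variant <- function(spec) {
  spec <- trimws(spec)
  if (spec == "" || identical(tolower(spec), "baseline")) return(model_variant())
  parts <- trimws(strsplit(spec, ",")[[1]])
  bad <- setdiff(parts, c("pf", "pf_c3k2", "dmae", "aifi"))
  if (length(bad) > 0) stop("unknown variant component(s): ", paste(bad, collapse = ", "))
  model_variant(pf_c3k2 = any(parts %in% c("pf", "pf_c3k2")),
                dmae = "dmae" %in% parts, aifi = "aifi" %in% parts)
}

# One layer-graph entry.
gl <- function(name, from, kind, mod = NULL) {
  list(name = name, from = from, kind = kind, mod = mod)
}

#' Build a detector
#'
#' Assembles the network at YOLO11n scale for a given [model_variant()].
#' Parameter initialization is a pure function of `seed`; the analytic FLOPs
#' of the result depend only on the architecture.
#'
#' @param variant a [model_variant()] (or a string for [parse_variant()]).
#' @param num_classes number of object classes (5 for the pest task).
#' @param imgsz square input size in pixels used by [predict_image()] and
#'   training.
#' @param seed integer seed controlling parameter initialization.
#' @param dmae_reduction channel-reduction divisor of the DMAE branches.
#' @param aifi_hidden,aifi_heads MLP hidden width and head count of AIFI.
#' @return a `pda_model` environment.
#' @export
build_model <- function(variant = model_variant(), num_classes = 5L,
                        imgsz = 640L, seed = 0L, dmae_reduction = 3L,
                        aifi_hidden = 512L, aifi_heads = 8L) {
  if (is.character(variant)) variant <- parse_variant(variant)
  stopifnot(num_classes >= 1)
  set.seed(seed)
  c3k2 <- function(cin, cout, flag, e = 0.5) {
    new_c3k2(cin, cout, n = 1L, mode_flag = flag, e = e,
             variant = if (variant$pf_c3k2) "pf" else "baseline")
  }
  spp <- if (variant$aifi) {
    new_aifi(aifi_config(embed_dim = 256L, heads = aifi_heads, hidden = aifi_hidden))
  } else {
    new_sppf(256L, 256L)
  }
  layers <- list(
    gl("stem0", "input", "module", new_conv(3L, 16L, k = 3L, s = 2L)),
    gl("stem1", "stem0", "module", new_conv(16L, 32L, k = 3L, s = 2L)),
    gl("b2", "stem1", "module", c3k2(32L, 64L, FALSE, e = 0.25)),
    gl("down3", "b2", "module", new_conv(64L, 64L, k = 3L, s = 2L)),
    gl("b4", "down3", "module", c3k2(64L, 128L, FALSE, e = 0.25)),
    gl("down5", "b4", "module", new_conv(128L, 128L, k = 3L, s = 2L)),
    gl("b6", "down5", "module", c3k2(128L, 128L, TRUE)),
    gl("down7", "b6", "module", new_conv(128L, 256L, k = 3L, s = 2L)),
    gl("b8", "down7", "module", c3k2(256L, 256L, TRUE)),
    gl("spp", "b8", "module", spp),
    gl("psa", "spp", "module", new_c2psa(256L, n = 1L)),
    gl("up1", "psa", "upsample"),
    gl("cat1", c("up1", "b6"), "concat"),
    gl("n13", "cat1", "module", c3k2(384L, 128L, FALSE)),
    gl("up2", "n13", "upsample"),
    gl("cat2", c("up2", "b4"), "concat"),
    gl("n16", "cat2", "module", c3k2(256L, 64L, FALSE)),
    gl("d17", "n16", "module", new_conv(64L, 64L, k = 3L, s = 2L)),
    gl("cat3", c("d17", "n13"), "concat"),
    gl("n19", "cat3", "module", c3k2(192L, 128L, FALSE)),
    gl("d20", "n19", "module", new_conv(128L, 128L, k = 3L, s = 2L)),
    gl("cat4", c("d20", "psa"), "concat"),
    gl("n22", "cat4", "module", c3k2(384L, 256L, TRUE))
  )
  heads_in <- c("n16", "n19", "n22")
  if (variant$dmae) {
    for (i in seq_along(heads_in)) {
      ch <- c(64L, 128L, 256L)[i]
      nm <- paste0("dmae_p", i + 2L)
      layers[[length(layers) + 1L]] <-
        gl(nm, heads_in[i], "module",
           new_dmae(dmae_config(ch, reduction = dmae_reduction)))
      heads_in[i] <- nm
    }
  }
  layers[[length(layers) + 1L]] <-
    gl("detect", heads_in, "detect",
       new_detect_head(c(64L, 128L, 256L), num_classes))

  model <- new.env(parent = emptyenv())
  model$layers <- layers
  model$nc <- as.integer(num_classes)
  model$variant <- variant
  model$strides <- c(8L, 16L, 32L)
  model$imgsz <- as.integer(imgsz)
  model$seed <- as.integer(seed)
  class(model) <- "pda_model"
  model
}

layer_modules <- function(model) {
  mods <- lapply(model$layers, function(l) l$mod)
  mods[!vapply(mods, is.null, logical(1))]
}

#' @export
print.pda_model <- function(x, ...) {
  v <- x$variant
  tags <- c(if (v$pf_c3k2) "PF_C3k2", if (v$dmae) "DMAE", if (v$aifi) "AIFI")
  cat("<pda_model> YOLO11n-scale detector (",
      if (length(tags)) paste(tags, collapse = " + ") else "baseline",
      "), ", x$nc, " classes, ", length(x$layers), " graph nodes, ",
      format(model_n_params(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Census of module types in a model
#'
#' Recursively tabulates the type labels of every module in the layer graph
#' (e.g. `c3k2`, `pf_c3k2`, `sppf`, `aifi`, `dmae`).
#'
#' @param model a `pda_model`.
#' @return named integer table of type counts.
#' @export
model_census <- function(model) {
  table(unlist(lapply(layer_modules(model), module_census)))
}

#' @rdname model_census
#' @export
model_n_params <- function(model) {
  sum(vapply(layer_modules(model), mod_n_params, numeric(1)))
}

#' @rdname model_census
#' @export
model_param_sum <- function(model) {
  sum(vapply(layer_modules(model), mod_param_sum, numeric(1)))
}

## ---- forward / backward over the graph ---------------------------------

model_forward <- function(model, x, keep = FALSE) {
  outs <- list(input = x)
  for (l in model$layers) {
    y <- switch(l$kind,
      module = l$mod$forward(outs[[l$from]]),
      upsample = upsample2x_nearest(outs[[l$from]]),
      concat = {
        ins <- lapply(l$from, function(nm) outs[[nm]])
        d <- dim(ins[[1]])
        array(unlist(ins, use.names = FALSE),
              dim = c(d[1], d[2], sum(vapply(ins, function(a) dim(a)[3], numeric(1)))))
      },
      detect = l$mod$forward(lapply(l$from, function(nm) outs[[nm]])),
      stop("unknown layer kind ", l$kind))
    outs[[l$name]] <- y
  }
  if (keep) model$.outs <- outs
  outs$detect
}

model_backward <- function(model, dys) {
  outs <- model$.outs
  grads <- list()
  add_grad <- function(nm, g) {
    grads[[nm]] <<- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  }
  grads$detect <- dys
  for (l in rev(model$layers)) {
    g <- grads[[l$name]]
    if (is.null(g)) next
    switch(l$kind,
      module = add_grad(l$from, l$mod$backward(g)),
      upsample = add_grad(l$from, upsample2x_nearest_grad(g)),
      concat = {
        off <- 0L
        for (nm in l$from) {
          ci <- dim(outs[[nm]])[3]
          add_grad(nm, g[, , off + seq_len(ci), drop = FALSE])
          off <- off + ci
        }
      },
      detect = {
        dxs <- l$mod$backward(g)
        for (i in seq_along(l$from)) add_grad(l$from[i], dxs[[i]])
      })
    grads[[l$name]] <- NULL
  }
  invisible(NULL)
}

model_zero_grad <- function(model) {
  for (mod in layer_modules(model)) mod_zero_grad(mod)
  invisible(model)
}

model_sgd_step <- function(model, lr, momentum = 0, weight_decay = 0) {
  for (mod in layer_modules(model)) mod_sgd_step(mod, lr, momentum, weight_decay)
  invisible(model)
}

## ---- FLOPs accounting --------------------------------------------------

#' Analytic FLOPs and parameter count
#'
#' Walks the layer graph with symbolic shapes and sums per-layer floating
#' point operations under the fused counting convention: one multiply plus
#' one add per multiply-accumulate of every convolution / linear layer
#' (batch-norm folded into the convolution), parameter-free operations
#' (pooling, activations, normalization, upsampling, attention softmax and
#' its matrix products) not counted. This convention reproduces the
#' complexity figures commonly reported for this detector family.
#'
#' @param model a `pda_model`.
#' @param input_size square input size in pixels (640 for reference numbers).
#' @return a `pda_model_stats` list: `gflops` (units of 1e9), `params`,
#'   `input_size`, and a per-layer breakdown tibble.
#' @export
count_flops <- function(model, input_size = 640L) {
  shapes <- list(input = c(input_size, input_size, 3L))
  total <- 0
  rows <- list()
  for (l in model$layers) {
    f <- 0
    sh <- switch(l$kind,
      module = {
        s <- shapes[[l$from]]
        r <- l$mod$flops(s[1], s[2])
        f <- r$flops
        c(r$h, r$w, l$mod$cout)
      },
      upsample = {
        s <- shapes[[l$from]]
        c(s[1] * 2L, s[2] * 2L, s[3])
      },
      concat = {
        ss <- lapply(l$from, function(nm) shapes[[nm]])
        c(ss[[1]][1], ss[[1]][2], sum(vapply(ss, function(s) s[3], numeric(1))))
      },
      detect = {
        for (i in seq_along(l$from)) {
          s <- shapes[[l$from[i]]]
          f <- f + l$mod$flops_scale(i, s[1], s[2])
        }
        c(0L, 0L, 0L)
      })
    shapes[[l$name]] <- sh
    total <- total + f
    rows[[length(rows) + 1L]] <- tibble::tibble(layer = l$name, kind = l$kind,
                                                flops = f)
  }
  structure(list(gflops = total / 1e9, params = model_n_params(model),
                 input_size = as.integer(input_size),
                 by_layer = dplyr::bind_rows(rows)),
            class = "pda_model_stats")
}

#' @export
print.pda_model_stats <- function(x, ...) {
  cat(sprintf("<pda_model_stats> %.3f GFLOPs at %dx%d, %s parameters\n",
              x$gflops, x$input_size, x$input_size,
              format(x$params, big.mark = ",")))
  invisible(x)
}

#' FLOPs of every ablation variant
#'
#' Builds each requested combination of the three modifications and runs
#' [count_flops()] on it.
#'
#' @param combinations list of [model_variant()]s; default all eight.
#' @param input_size input size in pixels.
#' @param num_classes class count.
#' @param ... passed to [build_model()].
#' @return tibble with the switch columns and `gflops`.
#' @export
flops_ledger <- function(combinations = NULL, input_size = 640L,
                         num_classes = 5L, ...) {
  if (is.null(combinations)) {
    combinations <- list()
    for (p in c(FALSE, TRUE)) for (d in c(FALSE, TRUE)) for (a in c(FALSE, TRUE))
      combinations[[length(combinations) + 1L]] <- model_variant(p, d, a)
  }
  purrr::map_dfr(combinations, function(v) {
    st <- count_flops(build_model(v, num_classes = num_classes, ...), input_size)
    tibble::tibble(pf_c3k2 = v$pf_c3k2, dmae = v$dmae, aifi = v$aifi,
                   gflops = st$gflops, params = st$params)
  })
}
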