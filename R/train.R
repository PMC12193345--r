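# CPU training. The loss is standard anchor-free one-stage plumbing: each
# ground-truth box is assigned to the cell containing its center at every
# scale; classification uses binary cross-entropy over all cells, box
# regression uses the distribution-focal cross-entropy over the 16 DFL bins
# of the four cell-unit distances at positive cells.

#' Training configuration
#'
#' Defaults follow the study's hyperparameter table: 150 epochs, batch 16,
#' learning rate 0.01, SGD with momentum 0.937 and weight decay 5e-4,
#' 640 x 640 input.
#'
#' @param epochs,batch,lr,optimizer,image_size,momentum,weight_decay,seed
#'   training hyperparameters.
#' @param warmup_epochs linear learning-rate ramp length (stabilizes the
#'   first SGD steps; set 0 to disable).
#' @param clip_norm global gradient-norm clip.
#' @return a `pda_train_config` list.
#' @export
train_config <- function(epochs = 150L, batch = 16L, lr = 0.01,
                         optimizer = "SGD", image_size = 640L,
                         momentum = 0.937, weight_decay = 0.0005,
                         seed = 0L, warmup_epochs = 3L, clip_norm = 5) {
  stopifnot(epochs >= 1, batch >= 1, lr > 0, image_size >= 32)
  if (!identical(toupper(optimizer), "SGD"))
    stop("only the SGD optimizer is supported")
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, optimizer = "SGD",
                 image_size = as.integer(image_size), momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 warmup_epochs = as.integer(warmup_epochs),
                 clip_norm = clip_norm),
            class = "pda_train_config")
}

# Loss and head-output gradients for one image.
detection_loss <- function(outs, ann, imgsz, strides, nc) {
  loss_cls <- 0; loss_box <- 0
  n_cls_entries <- 0; n_pos <- 0
  grads <- vector("list", length(outs))
  pos_list <- vector("list", length(outs))
  for (i in seq_along(outs)) {
    d <- dim(outs[[i]]$cls)
    n_cls_entries <- n_cls_entries + prod(d)
    if (nrow(ann) > 0) {
      s <- strides[i]
      gx <- ann$cx * imgsz / s; gy <- ann$cy * imgsz / s
      ix <- pmin(pmax(floor(gx), 0), d[2] - 1)
      iy <- pmin(pmax(floor(gy), 0), d[1] - 1)
      hw <- ann$w * imgsz / s / 2; hh <- ann$h * imgsz / s / 2
      eps <- 1e-3
      pos_list[[i]] <- data.frame(
        iy = iy + 1, ix = ix + 1, cls = ann$class_id + 1L,
        l = pmin(pmax((ix + 0.5) - (gx - hw), eps), DFL_BINS - 1 - eps),
        t = pmin(pmax((iy + 0.5) - (gy - hh), eps), DFL_BINS - 1 - eps),
        r = pmin(pmax((gx + hw) - (ix + 0.5), eps), DFL_BINS - 1 - eps),
        b = pmin(pmax((gy + hh) - (iy + 0.5), eps), DFL_BINS - 1 - eps))
      n_pos <- n_pos + nrow(ann)
    }
  }
  norm_cls <- max(n_pos, 1)
  for (i in seq_along(outs)) {
    d <- dim(outs[[i]]$cls)
    target <- array(0, dim = d)
    pp <- pos_list[[i]]
    if (!is.null(pp)) target[cbind(pp$iy, pp$ix, pp$cls)] <- 1
    z <- outs[[i]]$cls
    p <- stats::plogis(z)
    loss_cls <- loss_cls + sum(ifelse(target > 0, -log(pmax(p, 1e-12)),
                                      -log(pmax(1 - p, 1e-12))))
    dcls <- (p - target) / norm_cls
    dbox <- array(0, dim = dim(outs[[i]]$box))
    if (!is.null(pp) && nrow(pp) > 0 && n_pos > 0) {
      bd <- dim(outs[[i]]$box)
      logits <- array(outs[[i]]$box, dim = c(bd[1] * bd[2], DFL_BINS, 4L))
      dflat <- array(0, dim = dim(logits))
      cells <- (pp$ix - 1) * bd[1] + pp$iy
      dists <- as.matrix(pp[, c("l", "t", "r", "b")])
      for (side in 1:4) {
        zl <- matrix(logits[cells, , side], length(cells), DFL_BINS)
        pr <- softmax_rows(zl)
        tl <- floor(dists[, side]); wr <- dists[, side] - tl; wl <- 1 - wr
        tdist <- matrix(0, length(cells), DFL_BINS)
        tdist[cbind(seq_along(cells), tl + 1)] <- wl
        tdist[cbind(seq_along(cells), tl + 2)] <-
          tdist[cbind(seq_along(cells), tl + 2)] + wr
        loss_box <- loss_box - sum(tdist * log(pmax(pr, 1e-12)))
        dflat[cells, , side] <- dflat[cells, , side] +
          (pr - tdist) / (4 * n_pos)
      }
      dbox <- array(dflat, dim = bd)
    }
    grads[[i]] <- list(box = dbox, cls = dcls)
  }
  list(loss = loss_cls / norm_cls +
         if (n_pos > 0) loss_box / (4 * n_pos) else 0,
       grads = grads)
}

clip_gradients <- function(model, max_norm) {
  leaves <- unlist(lapply(layer_modules(model), mod_leaves), recursive = FALSE)
  sq <- 0
  for (leaf in leaves) for (p in leaf$param_names) {
    g <- leaf$grad[[p]]
    if (!is.null(g)) sq <- sq + sum(g^2)
  }
  nrm <- sqrt(sq)
  if (is.finite(nrm) && nrm > max_norm) {
    sc <- max_norm / nrm
    for (leaf in leaves) for (p in leaf$param_names) {
      if (!is.null(leaf$grad[[p]])) leaf$grad[[p]] <- leaf$grad[[p]] * sc
    }
  }
  invisible(nrm)
}

# Accepts a manifest (list or yaml path) or an in-memory list of samples,
# each `list(image = <h x w x 3 array>, annotations = <tibble>)`.
load_training_samples <- function(data, split, image_size) {
  if (is.list(data) && !is.null(data[[1]][["image"]])) {
    samples <- data
  } else {
    man <- if (is.character(data)) read_manifest(data) else data
    img_dir <- man[[split]]$images
    lbl_dir <- man[[split]]$labels
    if (is.null(img_dir) || !dir.exists(img_dir))
      stop("manifest split '", split, "' has no readable image directory")
    files <- sort(list.files(img_dir, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("empty split '", split, "': no PNG images in ", img_dir)
    samples <- lapply(files, function(f) {
      lbl <- file.path(lbl_dir, sub("\\.png$", ".txt", basename(f)))
      if (!file.exists(lbl)) stop("missing label file ", lbl)
      list(image = read_image_png(f), annotations = read_yolo_labels(lbl))
    })
  }
  lapply(samples, function(s) {
    d <- dim(s$image)
    if (d[1] != image_size || d[2] != image_size)
      s$image <- bilinear_resize(s$image, image_size, image_size)
    s
  })
}

#' Train a detector
#'
#' Full-network SGD training on CPU. Deterministic for a fixed
#' `config$seed` (which controls sample shuffling; parameter initialization
#' is fixed by the seed given to [build_model()]).
#'
#' @param model a `pda_model` from [build_model()].
#' @param data a dataset manifest (list or path to its YAML) or an in-memory
#'   list of `list(image, annotations)` samples.
#' @param config a [train_config()].
#' @param split which manifest split to train on.
#' @param verbose print per-epoch losses.
#' @return a `pda_training` object: the model (updated in place), a per-epoch
#'   `log` tibble, and the echoed configuration.
#' @export
train_model <- function(model, data, config = train_config(), split = "train",
                        verbose = FALSE) {
  samples <- load_training_samples(data, split, config$image_size)
  for (s in samples) {
    bad <- s$annotations$class_id >= model$nc | s$annotations$class_id < 0
    if (any(bad)) stop("class index out of range (nc = ", model$nc, ") in sample labels")
  }
  set.seed(config$seed)
  n <- length(samples)
  log_rows <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    lr_ep <- if (config$warmup_epochs > 0 && ep <= config$warmup_epochs)
      config$lr * ep / config$warmup_epochs else config$lr
    ep_loss <- 0
    for (start in seq(1, n, by = config$batch)) {
      idx <- ord[start:min(start + config$batch - 1L, n)]
      model_zero_grad(model)
      for (ii in idx) {
        s <- samples[[ii]]
        outs <- model_forward(model, s$image, keep = TRUE)
        dl <- detection_loss(outs, s$annotations, config$image_size,
                             model$strides, model$nc)
        ep_loss <- ep_loss + dl$loss
        scale <- 1 / length(idx)
        dys <- lapply(dl$grads, function(g)
          list(box = g$box * scale, cls = g$cls * scale))
        model_backward(model, dys)
      }
      clip_gradients(model, config$clip_norm)
      model_sgd_step(model, lr_ep, config$momentum, config$weight_decay)
    }
    log_rows[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / n, lr = lr_ep)
    if (verbose) message(sprintf("epoch %3d  loss %.5f  lr %.4g",
                                 ep, ep_loss / n, lr_ep))
  }
  structure(list(model = model, log = dplyr::bind_rows(log_rows),
                 config = config), class = "pda_training")
}

#' @export
print.pda_training <- function(x, ...) {
  cfg <- x$config
  cat("<pda_training>\n")
  cat(sprintf("  epochs=%d batch=%d lr=%g optimizer=%s image_size=%dx%d momentum=%g weight_decay=%g seed=%d\n",
              cfg$epochs, cfg$batch, cfg$lr, cfg$optimizer, cfg$image_size,
              cfg$image_size, cfg$momentum, cfg$weight_decay, cfg$seed))
  cat(sprintf("  initial loss %.5f -> final loss %.5f\n",
              x$log$loss[1], x$log$loss[nrow(x$log)]))
  invisible(x)
}

#' @rdname train_model
#' @param x a `pda_training` object.
#' @param ... unused.
#' @export
tidy.pda_training <- function(x, ...) x$log

#' @rdname train_model
#' @export
glance.pda_training <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), initial_loss = x$log$loss[1],
                 final_loss = x$log$loss[nrow(x$log)],
                 lr = x$config$lr, batch = x$config$batch,
                 image_size = x$config$image_size, seed = x$config$seed)
}

#' @rdname train_model
#' @param object a `pda_training` object.
#' @export
autoplot.pda_training <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}
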