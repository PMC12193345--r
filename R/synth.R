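# Synthetic trap-bottle scene generator. Emulates the imaging scenario of
# the pest dataset: the circular floor of a transparent cylindrical
# collection bottle (physical radius 4 cm) photographed from above, littered
# with wheat kernels and debris, carrying 1-8 insects from five species whose
# pixel body lengths follow the per-species body-length ranges (in mm) times
# an imaging scale. Labels are the minimum axis-aligned enclosing rectangles
# of the rendered insect masks, in normalized YOLO format. Everything is a
# deterministic function of the seed; no claim of photorealism is made.

PEST_CLASSES <- c("LGB", "RFB", "IMM", "MW", "AGM")

#' Species size table
#'
#' Per-class adult body-length ranges in millimetres (LGB 2.3-3.0,
#' RFB 2.3-4.4, IMM 8.0-10.0, MW 2.5-4.5, AGM 4.0-6.0).
#'
#' @return tibble with `class_id`, `name`, `len_min_mm`, `len_max_mm`,
#'   `moth` (moth-shaped species get wing shading).
#' @export
species_table <- function() {
  tibble::tibble(
    class_id = 0:4,
    name = PEST_CLASSES,
    len_min_mm = c(2.3, 2.3, 8.0, 2.5, 4.0),
    len_max_mm = c(3.0, 4.4, 10.0, 4.5, 6.0),
    moth = c(FALSE, FALSE, TRUE, FALSE, TRUE))
}

#' Scene specification
#'
#' @param image_w,image_h image size in pixels (native 1100 x 1080).
#' @param bottle_radius_mm physical bottle-floor radius (40 mm).
#' @param px_per_mm imaging scale; 6 px/mm puts the 40 mm bottle floor
#'   (240 px radius) comfortably inside the native frame.
#' @param insects_min,insects_max insects per scene (1-8).
#' @param kernels_min,kernels_max wheat kernels per scene.
#' @param debris_min,debris_max debris specks per scene.
#' @param scale global resolution factor applied to image size and
#'   px_per_mm; annotation counts and split arithmetic are scale-invariant.
#' @return a `pda_scene_spec` list.
#' @export
scene_spec <- function(image_w = 1100L, image_h = 1080L, bottle_radius_mm = 40,
                       px_per_mm = 6, insects_min = 1L, insects_max = 8L,
                       kernels_min = 12L, kernels_max = 35L,
                       debris_min = 20L, debris_max = 60L, scale = 1) {
  stopifnot(insects_min >= 1, insects_max <= 8, insects_min <= insects_max,
            scale > 0, px_per_mm > 0)
  structure(list(image_w = as.integer(round(image_w * scale)),
                 image_h = as.integer(round(image_h * scale)),
                 bottle_radius_mm = bottle_radius_mm,
                 px_per_mm = px_per_mm * scale,
                 insects_min = as.integer(insects_min),
                 insects_max = as.integer(insects_max),
                 kernels_min = as.integer(kernels_min),
                 kernels_max = as.integer(kernels_max),
                 debris_min = as.integer(debris_min),
                 debris_max = as.integer(debris_max),
                 species = species_table()),
            class = "pda_scene_spec")
}

with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

# Paint a filled rotated ellipse into (h, w, 3) image channels; returns the
# image and the painted pixel extents (used for enclosing-box labels).
draw_ellipse <- function(img, cx, cy, a, b, theta, col, soften = 0.25) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- max(a, b)
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(list(img = img, extent = NULL))
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(rep(xs - cx, each = length(ys)), length(ys))
  gy <- matrix(rep(ys - cy, times = length(xs)), length(ys))
  u <- (cos(theta) * gx + sin(theta) * gy) / a
  v <- (-sin(theta) * gx + cos(theta) * gy) / b
  d2 <- u^2 + v^2
  inside <- d2 <= 1
  if (!any(inside)) return(list(img = img, extent = NULL))
  alpha <- pmin(1, pmax(0, (1 - d2) / soften))
  alpha[!inside] <- 0
  for (ch in 1:3) {
    patch <- img[ys, xs, ch]
    img[ys, xs, ch] <- patch * (1 - alpha) + col[ch] * alpha
  }
  ij <- which(inside, arr.ind = TRUE)
  list(img = img,
       extent = c(x_min = xs[min(ij[, 2])], x_max = xs[max(ij[, 2])],
                  y_min = ys[min(ij[, 1])], y_max = ys[max(ij[, 1])]))
}

merge_extent <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  c(x_min = min(a["x_min"], b["x_min"]), x_max = max(a["x_max"], b["x_max"]),
    y_min = min(a["y_min"], b["y_min"]), y_max = max(a["y_max"], b["y_max"]))
}

draw_insect <- function(img, cx, cy, len_px, theta, moth) {
  body_col <- c(0.16, 0.10, 0.06) + runif(1, -0.03, 0.03)
  # never let a body collapse below pixel size at coarse rendering scales
  half_len <- max(len_px / 2, 0.9)
  half_wid <- max(len_px * ifelse(moth, 0.16, 0.19), 0.9)
  r1 <- draw_ellipse(img, cx, cy, half_len, half_wid, theta, body_col)
  img <- r1$img; ext <- r1$extent
  # head: small ellipse at one end
  hx <- cx + cos(theta) * half_len * 0.85
  hy <- cy + sin(theta) * half_len * 0.85
  r2 <- draw_ellipse(img, hx, hy, half_wid * 0.8, half_wid * 0.7, theta,
                     body_col * 0.8)
  img <- r2$img; ext <- merge_extent(ext, r2$extent)
  if (moth) {
    # lighter elongated wing shading over the abdomen
    wing_col <- c(0.55, 0.47, 0.35)
    r3 <- draw_ellipse(img, cx - cos(theta) * half_len * 0.15,
                       cy - sin(theta) * half_len * 0.15,
                       half_len * 0.75, half_wid * 0.75, theta, wing_col,
                       soften = 0.5)
    img <- r3$img; ext <- merge_extent(ext, r3$extent)
  }
  list(img = img, extent = ext)
}

#' Generate one trap-bottle scene
#'
#' Renders the bottle-floor disc, wheat kernels, debris specks and 1-8
#' insects, and returns the image with one annotation per insect (minimum
#' axis-aligned enclosing rectangle of the rendered insect, normalized
#' center/size). Byte-identical output for a fixed `(spec, seed)`.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed.
#' @param max_retries placement attempts per insect before giving up.
#' @return list with `image` (`h x w x 3` array in `[0, 1]`) and
#'   `annotations` (tibble `class_id, cx, cy, w, h`).
#' @export
generate_scene <- function(spec, seed, max_retries = 50L) {
  with_preserved_rng(seed, {
    h <- spec$image_h; w <- spec$image_w
    img <- array(rep(c(0.13, 0.12, 0.11), each = h * w), dim = c(h, w, 3))
    ccx <- w / 2; ccy <- h / 2
    rad <- spec$bottle_radius_mm * spec$px_per_mm
    # bottle floor: bright translucent disc with a darker rim
    ys <- seq_len(h); xs <- seq_len(w)
    dist2 <- outer((ys - ccy)^2, (xs - ccx)^2, "+")
    disc <- dist2 <= rad^2
    shade <- 0.78 - 0.10 * sqrt(dist2) / rad
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[disc] <- (shade * c(1, 0.99, 0.96)[ch])[disc]
      img[, , ch] <- plane
    }
    rim <- dist2 > (0.96 * rad)^2 & dist2 <= rad^2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[rim] <- plane[rim] * 0.6
      img[, , ch] <- plane
    }
    place_in_disc <- function(margin, retries = max_retries) {
      if (margin < rad) {
        for (try in seq_len(retries)) {
          px <- runif(1, ccx - rad, ccx + rad)
          py <- runif(1, ccy - rad, ccy + rad)
          if ((px - ccx)^2 + (py - ccy)^2 <= (rad - margin)^2) return(c(px, py))
        }
      }
      NULL
    }
    # wheat kernels: tan ellipses ~6 mm long
    n_k <- sample(spec$kernels_min:spec$kernels_max, 1)
    for (i in seq_len(n_k)) {
      klen <- runif(1, 5, 7) * spec$px_per_mm / 2
      kwid <- klen * runif(1, 0.42, 0.55)
      pos <- place_in_disc(klen)
      if (is.null(pos)) next
      col <- c(0.72, 0.58, 0.33) * runif(1, 0.85, 1.1)
      img <- draw_ellipse(img, pos[1], pos[2], klen, kwid,
                          runif(1, 0, pi), pmin(col, 1))$img
    }
    # debris: small dark specks
    n_d <- sample(spec$debris_min:spec$debris_max, 1)
    for (i in seq_len(n_d)) {
      dl <- runif(1, 0.3, 1.2) * spec$px_per_mm
      pos <- place_in_disc(dl)
      if (is.null(pos)) next
      col <- c(0.45, 0.36, 0.22) * runif(1, 0.6, 1.1)
      img <- draw_ellipse(img, pos[1], pos[2], dl, dl * runif(1, 0.5, 1),
                          runif(1, 0, pi), pmin(col, 1))$img
    }
    # insects
    k <- sample(spec$insects_min:spec$insects_max, 1)
    cls <- sample(0:4, k, replace = TRUE)
    ann <- vector("list", k)
    for (i in seq_len(k)) {
      row <- spec$species[spec$species$class_id == cls[i], ]
      len_px <- runif(1, row$len_min_mm, row$len_max_mm) * spec$px_per_mm
      pos <- place_in_disc(len_px / 2 + 2)
      if (is.null(pos))
        stop("could not place insect ", i, " inside the bottle disc after ",
             max_retries, " attempts")
      r <- draw_insect(img, pos[1], pos[2], len_px, runif(1, 0, pi), row$moth)
      img <- r$img
      ext <- r$extent
      ann[[i]] <- tibble::tibble(
        class_id = cls[i],
        cx = (ext["x_min"] + ext["x_max"]) / 2 / w,
        cy = (ext["y_min"] + ext["y_max"]) / 2 / h,
        w = (ext["x_max"] - ext["x_min"] + 1) / w,
        h = (ext["y_max"] - ext["y_min"] + 1) / h)
    }
    list(image = img, annotations = dplyr::bind_rows(ann))
  })
}

## ---- augmentation ------------------------------------------------------

#' Augment an image and its annotations
#'
#' The four augmentation operations applied to the training split:
#' horizontal flip (`cx -> 1 - cx`), vertical flip (`cy -> 1 - cy`),
#' brightness reduction (scale by `factor`, clamp), and additive Gaussian
#' pixel noise (zero mean, `sigma` on the 8-bit scale, seeded, clamp).
#' The photometric operations leave annotations untouched.
#'
#' @param image `h x w x 3` array in `[0, 1]`.
#' @param annotations tibble `class_id, cx, cy, w, h`.
#' @param op_name one of `"hflip"`, `"vflip"`, `"brightness_down"`,
#'   `"gauss_noise"`.
#' @param factor brightness factor (< 1).
#' @param sigma noise standard deviation in 8-bit intensity units.
#' @param seed seed for the noise draw.
#' @return list with the transformed `image` and `annotations`.
#' @export
augment_image <- function(image, annotations, op_name, factor = 0.6,
                          sigma = 10, seed = 0L) {
  d <- dim(image)
  switch(op_name,
    hflip = {
      image <- image[, d[2]:1, , drop = FALSE]
      annotations$cx <- 1 - annotations$cx
    },
    vflip = {
      image <- image[d[1]:1, , , drop = FALSE]
      annotations$cy <- 1 - annotations$cy
    },
    brightness_down = {
      image <- pmin(pmax(image * factor, 0), 1)
    },
    gauss_noise = {
      image <- with_preserved_rng(seed, {
        pmin(pmax(image + array(rnorm(prod(d), 0, sigma / 255), dim = d), 0), 1)
      })
    },
    stop("unknown augmentation op: ", op_name)
  )
  list(image = image, annotations = annotations)
}

AUG_OPS <- c("hflip", "vflip", "brightness_down", "gauss_noise")

## ---- YOLO label and image I/O ------------------------------------------

#' Read and write YOLO-format label files
#'
#' One line per object: `class cx cy w h` with normalized coordinates in
#' 6-decimal fixed point. `read_yolo_labels()` validates every line and
#' reports the offending line number on malformed input.
#'
#' @param annotations tibble `class_id, cx, cy, w, h`.
#' @param path label file path.
#' @return `read_yolo_labels()`: the annotations tibble.
#' @export
write_yolo_labels <- function(annotations, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", annotations$class_id,
                   annotations$cx, annotations$cy, annotations$w,
                   annotations$h)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_labels
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(class_id = integer(), cx = numeric(), cy = numeric(),
                          w = numeric(), h = numeric()))
  }
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(parts) != 5L || anyNA(vals))
      stop("malformed YOLO label line ", i, " in ", path, ": '", lines[i], "'")
    vals
  })
  m <- do.call(rbind, rows)
  tibble::tibble(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                 w = m[, 4], h = m[, 5])
}

read_image_png <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

## ---- dataset materialization -------------------------------------------

#' Build a synthetic YOLO dataset
#'
#' Generates `n_images` scenes, splits them 7:1:2 into train/val/test by a
#' seeded shuffle, replaces every training image by its four augmented
#' variants (the originals are not retained in the training split, so
#' `n = 2000` yields final counts 5600/200/400), and writes PNG images,
#' YOLO label files and a dataset manifest YAML.
#'
#' @param n_images number of original scenes; must be divisible by 10.
#' @param spec a [scene_spec()].
#' @param out_dir output directory (created).
#' @param seed master seed; per-scene seeds are drawn from it.
#' @return a `pda_manifest` list (also written as `manifest.yaml`): class
#'   names, per-split directories and final image counts.
#' @export
build_dataset <- function(n_images, spec = scene_spec(), out_dir, seed = 0L) {
  if (n_images %% 10 != 0) stop("n_images must be divisible by 10 for the 7:1:2 split")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  splits <- split_indices(n_images, seed)
  for (s in names(splits)) {
    dir.create(file.path(out_dir, "images", s), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels", s), recursive = TRUE, showWarnings = FALSE)
  }
  scene_seeds <- with_preserved_rng(seed, sample.int(.Machine$integer.max - 1L, n_images))
  counts <- c(train = 0L, val = 0L, test = 0L)
  for (s in names(splits)) {
    for (i in splits[[s]]) {
      sc <- generate_scene(spec, scene_seeds[i])
      stem <- sprintf("img_%05d", i)
      if (s == "train") {
        for (op in AUG_OPS) {
          a <- augment_image(sc$image, sc$annotations, op, seed = scene_seeds[i] + 1L)
          png::writePNG(a$image, file.path(out_dir, "images", s,
                                           paste0(stem, "_", op, ".png")))
          write_yolo_labels(a$annotations,
                            file.path(out_dir, "labels", s,
                                      paste0(stem, "_", op, ".txt")))
          counts[s] <- counts[s] + 1L
        }
      } else {
        png::writePNG(sc$image, file.path(out_dir, "images", s, paste0(stem, ".png")))
        write_yolo_labels(sc$annotations,
                          file.path(out_dir, "labels", s, paste0(stem, ".txt")))
        counts[s] <- counts[s] + 1L
      }
    }
  }
  man <- list(names = PEST_CLASSES, nc = 5L,
              n_original = as.integer(n_images),
              counts = as.list(counts),
              train = list(images = file.path(out_dir, "images", "train"),
                           labels = file.path(out_dir, "labels", "train")),
              val = list(images = file.path(out_dir, "images", "val"),
                         labels = file.path(out_dir, "labels", "val")),
              test = list(images = file.path(out_dir, "images", "test"),
                          labels = file.path(out_dir, "labels", "test")))
  class(man) <- "pda_manifest"
  yaml::write_yaml(unclass(man), file.path(out_dir, "manifest.yaml"))
  man
}

#' @rdname build_dataset
#' @param n_images total scene count.
#' @export
split_indices <- function(n_images, seed = 0L) {
  ord <- with_preserved_rng(seed, sample.int(n_images))
  n_train <- (n_images * 7L) %/% 10L
  n_val <- n_images %/% 10L
  list(train = sort(ord[seq_len(n_train)]),
       val = sort(ord[n_train + seq_len(n_val)]),
       test = sort(ord[(n_train + n_val + 1L):n_images]))
}

#' @rdname build_dataset
#' @param path path to a `manifest.yaml`.
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  class(man) <- "pda_manifest"
  man
}

#' Display a scene with its boxes
#'
#' @param scene a list with `image` and `annotations` (as from
#'   [generate_scene()]), optionally with a `detections` tibble overlaid.
#' @param detections optional tibble of detections to draw in a second color.
#' @return a ggplot object.
#' @export
plot_scene <- function(scene, detections = NULL) {
  d <- dim(scene$image)
  boxes <- scene$annotations
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(aperm(scene$image, c(1, 2, 3)),
                               xmin = 0, xmax = d[2], ymin = 0, ymax = d[1]) +
    ggplot2::coord_fixed(xlim = c(0, d[2]), ylim = c(0, d[1]), expand = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void()
  if (nrow(boxes) > 0) {
    p <- p + ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(xmin = (.data$cx - .data$w / 2) * d[2],
                   xmax = (.data$cx + .data$w / 2) * d[2],
                   ymin = (.data$cy - .data$h / 2) * d[1],
                   ymax = (.data$cy + .data$h / 2) * d[1]),
      fill = NA, color = "green", linewidth = 0.4)
  }
  if (!is.null(detections) && nrow(detections) > 0) {
    p <- p + ggplot2::geom_rect(
      data = detections,
      ggplot2::aes(xmin = (.data$cx - .data$w / 2) * d[2],
                   xmax = (.data$cx + .data$w / 2) * d[2],
                   ymin = (.data$cy - .data$h / 2) * d[1],
                   ymax = (.data$cy + .data$h / 2) * d[1]),
      fill = NA, color = "red", linewidth = 0.4)
  }
  p
}
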