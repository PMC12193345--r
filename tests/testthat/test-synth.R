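# Synthetic trap-bottle scenes, augmentation, labels, dataset arithmetic.

small_spec <- scene_spec(scale = 0.12)

test_that("scene generation is deterministic under a fixed seed", {
  a <- generate_scene(small_spec, 7)
  b <- generate_scene(small_spec, 7)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations, b$annotations)
  d <- generate_scene(small_spec, 8)
  expect_false(identical(a$image, d$image))
})

test_that("every scene carries between 1 and 8 annotations with in-image boxes", {
  for (seed in 1:25) {
    sc <- generate_scene(small_spec, seed)
    k <- nrow(sc$annotations)
    expect_gte(k, 1); expect_lte(k, 8)
    with(sc$annotations, {
      expect_true(all(w > 0 & h > 0))
      expect_true(all(cx - w / 2 >= 0 & cx + w / 2 <= 1))
      expect_true(all(cy - h / 2 >= 0 & cy + h / 2 <= 1))
    })
  }
})

test_that("class-conditional box sizes respect the body-length ordering (IMM largest, LGB smallest)", {
  spec <- scene_spec(scale = 0.2)
  diag_px <- list()
  for (seed in 1:200) {
    sc <- generate_scene(spec, 5000 + seed)
    a <- sc$annotations
    d <- sqrt((a$w * spec$image_w)^2 + (a$h * spec$image_h)^2)
    for (i in seq_len(nrow(a))) {
      cl <- as.character(a$class_id[i])
      diag_px[[cl]] <- c(diag_px[[cl]], d[i])
    }
  }
  med <- vapply(as.character(0:4), function(cl) median(diag_px[[cl]]), numeric(1))
  expect_gt(med[["2"]], med[["0"]])             # IMM > LGB
  expect_equal(which.max(med), 3L, ignore_attr = TRUE)  # IMM largest overall
  expect_equal(which.min(med), 1L, ignore_attr = TRUE)  # LGB smallest overall
})

test_that("horizontal and vertical flips are involutions and transform labels by reflection", {
  sc <- generate_scene(small_spec, 3)
  ann <- tibble::tibble(class_id = 1L, cx = 0.2, cy = 0.7, w = 0.1, h = 0.1)
  h1 <- augment_image(sc$image, ann, "hflip")
  expect_equal(h1$annotations$cx, 0.8)
  expect_equal(h1$annotations$cy, 0.7)
  v1 <- augment_image(sc$image, ann, "vflip")
  expect_equal(v1$annotations$cy, 0.3)
  expect_equal(v1$annotations$cx, 0.2)
  h2 <- augment_image(h1$image, h1$annotations, "hflip")
  expect_identical(h2$image, sc$image)
  expect_equal(h2$annotations, ann)
  expect_error(augment_image(sc$image, ann, "rotate"), "unknown augmentation")
})

test_that("brightness reduction darkens every pixel; gaussian noise is seeded and clamped", {
  sc <- generate_scene(small_spec, 4)
  b <- augment_image(sc$image, sc$annotations, "brightness_down")
  expect_true(all(b$image <= sc$image + 1e-12))
  expect_identical(b$annotations, sc$annotations)
  g1 <- augment_image(sc$image, sc$annotations, "gauss_noise", seed = 5)
  g2 <- augment_image(sc$image, sc$annotations, "gauss_noise", seed = 5)
  expect_identical(g1$image, g2$image)
  expect_true(all(g1$image >= 0 & g1$image <= 1))
  expect_identical(g1$annotations, sc$annotations)
})

test_that("flipping the image moves the rendered insect pixels exactly as the flipped labels say", {
  spec <- scene_spec(scale = 0.25)
  for (seed in c(11, 12)) {
    sc <- generate_scene(spec, seed)
    fl <- augment_image(sc$image, sc$annotations, "hflip")
    w_px <- spec$image_w
    gray <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    dark_box <- function(img, a) {
      # tight extent of dark (insect-body) pixels inside the labelled box
      x0 <- max(1, floor((a$cx - a$w / 2) * dim(img)[2])); x1 <- ceiling((a$cx + a$w / 2) * dim(img)[2])
      y0 <- max(1, floor((a$cy - a$h / 2) * dim(img)[1])); y1 <- ceiling((a$cy + a$h / 2) * dim(img)[1])
      g <- gray(img)[y0:y1, x0:x1, drop = FALSE]
      idx <- which(g < 0.3, arr.ind = TRUE)
      if (nrow(idx) == 0) return(NULL)
      c(x_min = x0 + min(idx[, 2]) - 1, x_max = x0 + max(idx[, 2]) - 1)
    }
    for (i in seq_len(nrow(sc$annotations))) {
      e0 <- dark_box(sc$image, sc$annotations[i, ])
      e1 <- dark_box(fl$image, fl$annotations[i, ])
      if (is.null(e0) || is.null(e1)) next
      # mirrored pixel extents: x' = w + 1 - x
      expect_equal(unname(e1["x_min"]), w_px + 1 - unname(e0["x_max"]), tolerance = 1.01)
      expect_equal(unname(e1["x_max"]), w_px + 1 - unname(e0["x_min"]), tolerance = 1.01)
    }
  }
})

test_that("YOLO label lines use 6-decimal fixed point and round-trip within 5e-7", {
  tmp <- tempfile(fileext = ".txt")
  write_yolo_labels(tibble::tibble(class_id = 1L, cx = 0.5, cy = 0.5, w = 0.1, h = 0.2), tmp)
  expect_identical(readLines(tmp), "1 0.500000 0.500000 0.100000 0.200000")

  write_yolo_labels(tibble::tibble(class_id = integer(), cx = numeric(),
                                   cy = numeric(), w = numeric(), h = numeric()), tmp)
  back <- read_yolo_labels(tmp)
  expect_equal(nrow(back), 0)

  set.seed(61)
  ann <- tibble::tibble(class_id = sample(0:4, 100, TRUE), cx = runif(100),
                        cy = runif(100), w = runif(100), h = runif(100))
  write_yolo_labels(ann, tmp)
  rt <- read_yolo_labels(tmp)
  expect_identical(rt$class_id, ann$class_id)
  expect_lte(max(abs(as.matrix(rt[2:5]) - as.matrix(ann[2:5]))), 5e-7)

  writeLines(c("1 0.5 0.5 0.1 0.1", "2 0.4 bad 0.1 0.1"), tmp)
  expect_error(read_yolo_labels(tmp), "line 2")
})

test_that("splits are disjoint, exhaustive and in 7:1:2 proportion for any n divisible by 10", {
  for (n in c(20L, 50L, 2000L)) {
    sp <- split_indices(n, seed = 3)
    expect_equal(length(sp$train), n * 7 / 10)
    expect_equal(length(sp$val), n / 10)
    expect_equal(length(sp$test), n * 2 / 10)
    expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:n)
  }
})

test_that("build_dataset at n = 20 writes a 14/2/4 split with 56 augmented training images", {
  out <- file.path(tempdir(), "pda_ds20")
  unlink(out, recursive = TRUE)
  man <- build_dataset(20L, scene_spec(scale = 0.08), out, seed = 1)
  expect_equal(man$counts$train, 56L)
  expect_equal(man$counts$val, 2L)
  expect_equal(man$counts$test, 4L)
  expect_length(list.files(file.path(out, "images", "train"), pattern = "\\.png$"), 56)
  expect_length(list.files(file.path(out, "labels", "train"), pattern = "\\.txt$"), 56)
  expect_length(list.files(file.path(out, "images", "val")), 2)
  expect_length(list.files(file.path(out, "images", "test")), 4)
  # every training image is one of the four augmentations of an original
  ops <- sub("^img_\\d+_", "", sub("\\.png$", "", list.files(file.path(out, "images", "train"))))
  expect_setequal(unique(ops), c("hflip", "vflip", "brightness_down", "gauss_noise"))
  # manifest round-trips through YAML
  man2 <- read_manifest(file.path(out, "manifest.yaml"))
  expect_equal(man2$names, c("LGB", "RFB", "IMM", "MW", "AGM"))
  expect_error(build_dataset(15L, scene_spec(scale = 0.08), out), "divisible by 10")
  unlink(out, recursive = TRUE)
})
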