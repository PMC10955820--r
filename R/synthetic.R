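## Synthetic 10-class digit-glyph corpus: ten hand-designed stroke templates
## on a 28 x 28 canvas, rendered with random affine jitter, stroke width and
## clipped Gaussian pixel noise. The corpus gives the pipeline a
## self-contained, downloads-free stand-in for a handwritten-digit dataset;
## classes 4 and 9 share a vertical-stroke-plus-appendage structure on
## purpose so inter-class confusability is not trivial. Real MNIST IDX files
## can be read with read_idx() when available.

## x grows rightward (columns), y downward (rows); canvas coordinates 1..28.
arc_points <- function(cx, cy, rx, ry, from_deg, to_deg, n = 36L) {
  th <- seq(from_deg, to_deg, length.out = n) * pi / 180
  cbind(cx + rx * cos(th), cy + ry * sin(th))
}

glyph_templates <- function() {
  seg <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE)
  list(
    `0` = list(arc_points(14, 14, 6, 9.5, 0, 360)),
    `1` = list(seg(11, 8, 14, 4), seg(14, 4, 14, 24)),
    `2` = list(arc_points(14, 9, 5.5, 5, 180, 360),
               seg(19.5, 9, 8, 24), seg(8, 24, 20, 24)),
    `3` = list(arc_points(12, 8.5, 5.5, 4.5, 160, 405),
               arc_points(12, 18.5, 6, 5.5, -45, 200)),
    `4` = list(seg(16, 4, 7, 17), seg(7, 17, 22, 17), seg(16, 4, 16, 24)),
    `5` = list(seg(19, 4, 9, 4), seg(9, 4, 9, 12),
               arc_points(13, 17.5, 5.5, 6, -90, 150)),
    `6` = list(arc_points(16, 15, 7, 11, 280, 180),
               arc_points(13.5, 18.5, 5, 5.5, 0, 360)),
    `7` = list(seg(8, 5, 20, 5), seg(20, 5, 11, 24)),
    `8` = list(arc_points(14, 9, 4.5, 4.5, 0, 360),
               arc_points(14, 19, 5.5, 5.5, 0, 360)),
    `9` = list(arc_points(13, 9.5, 5, 5.5, 0, 360), seg(18, 9.5, 16.5, 24))
  )
}

## Rasterize jittered polylines onto a 28 x 28 canvas.
render_glyph <- function(strokes, rotation = 0, dx = 0, dy = 0, scale = 1,
                         stroke_width = 2, noise_sd = 0) {
  img <- matrix(0, 28L, 28L)
  ct <- cos(rotation); st <- sin(rotation)
  sigma <- stroke_width / 2.2
  rad <- max(1L, ceiling(2 * sigma))
  for (pl in strokes) {
    ## affine jitter about the canvas center
    x <- pl[, 1L] - 14.5; y <- pl[, 2L] - 14.5
    px <- (ct * x - st * y) * scale + 14.5 + dx
    py <- (st * x + ct * y) * scale + 14.5 + dy
    ## densify: sample along each segment at ~0.35 px steps
    for (s in seq_len(length(px) - 1L)) {
      len <- sqrt((px[s + 1L] - px[s])^2 + (py[s + 1L] - py[s])^2)
      t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.35)))
      qx <- px[s] + t * (px[s + 1L] - px[s])
      qy <- py[s] + t * (py[s + 1L] - py[s])
      for (q in seq_along(qx)) {
        c0 <- max(1L, floor(qx[q]) - rad):min(28L, floor(qx[q]) + rad + 1L)
        r0 <- max(1L, floor(qy[q]) - rad):min(28L, floor(qy[q]) + rad + 1L)
        if (!length(c0) || !length(r0)) next
        d2 <- outer((r0 - qy[q])^2, (c0 - qx[q])^2, "+")
        img[r0, c0] <- pmax(img[r0, c0], exp(-d2 / (2 * sigma^2)))
      }
    }
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(784L, sd = noise_sd), 28L, 28L)
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic digit-glyph image corpus
#'
#' Renders `n_per_class` jittered instances of each of the ten stroke
#' templates: random rotation, translation and scale within the given
#' ranges, random stroke width, plus additive Gaussian noise clipped so
#' pixels stay in `[0, 1]`. Deterministic given the seed. With
#' `n_test_per_class > 0` a disjoint test split is drawn from the same
#' stream.
#'
#' @param n_per_class Training images per class.
#' @param seed Integer seed.
#' @param rotation_deg,translate_px,scale_range,stroke_width_range,noise_sd
#'   Jitter ranges: rotation is uniform on +/- `rotation_deg` degrees,
#'   translation uniform on +/- `translate_px` pixels per axis, scale and
#'   stroke width uniform on their ranges, `noise_sd` the pixel noise
#'   standard deviation. Set all to zero to get identical images per class.
#' @param n_test_per_class Optional extra per-class test images.
#' @return With no test split: `list(images, labels)` where `images` is an
#'   `N x 28 x 28` array and `labels` an integer vector. Otherwise
#'   `list(train = ..., test = ...)` of two such lists.
#' @export
generate_glyph_dataset <- function(n_per_class, seed = 1L,
                                   rotation_deg = 15, translate_px = 2,
                                   scale_range = c(0.9, 1.1),
                                   stroke_width_range = c(1, 3),
                                   noise_sd = 0.05,
                                   n_test_per_class = 0L) {
  stopifnot(n_per_class >= 1L)
  tmpl <- glyph_templates()
  draw_set <- function(n_each) {
    N <- 10L * n_each
    images <- array(0, c(N, 28L, 28L))
    labels <- integer(N)
    i <- 0L
    for (cls in 0:9) {
      for (k in seq_len(n_each)) {
        i <- i + 1L
        images[i, , ] <- render_glyph(
          tmpl[[as.character(cls)]],
          rotation = runif(1, -rotation_deg, rotation_deg) * pi / 180,
          dx = runif(1, -translate_px, translate_px),
          dy = runif(1, -translate_px, translate_px),
          scale = runif(1, scale_range[1L], scale_range[2L]),
          stroke_width = runif(1, stroke_width_range[1L],
                               stroke_width_range[2L]),
          noise_sd = noise_sd)
        labels[i] <- cls
      }
    }
    list(images = images, labels = labels)
  }
  with_seed(seed, {
    train <- draw_set(as.integer(n_per_class))
    if (n_test_per_class > 0L) {
      list(train = train, test = draw_set(as.integer(n_test_per_class)))
    } else train
  })
}

#' Read an MNIST-dialect IDX image/label pair
#'
#' Big-endian IDX containers: magic 2051 for image files (dimensions
#' `N x 28 x 28`, one unsigned byte per pixel) and 2049 for label files.
#' Pixels are scaled to `[0, 1]` by division by 255; the two files must
#' agree on the number of items.
#'
#' @param images_path,labels_path Paths to the IDX files.
#' @return `list(images, labels)` as in [generate_glyph_dataset()].
#' @export
read_idx <- function(images_path, labels_path) {
  con <- file(images_path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, integer(), 1L, size = 4L, endian = "big")
  if (!identical(magic, 2051L)) {
    stop(sprintf("bad magic %d in image file (expected 2051)", magic),
         call. = FALSE)
  }
  dims <- readBin(con, integer(), 3L, size = 4L, endian = "big")
  if (any(dims < 0L) || dims[2L] != 28L || dims[3L] != 28L) {
    stop("image file must hold N x 28 x 28 images", call. = FALSE)
  }
  n <- dims[1L]
  px <- readBin(con, "raw", n * 784L)
  if (length(px) != n * 784L) stop("truncated image file", call. = FALSE)

  con2 <- file(labels_path, "rb")
  on.exit(close(con2), add = TRUE)
  magic2 <- readBin(con2, integer(), 1L, size = 4L, endian = "big")
  if (!identical(magic2, 2049L)) {
    stop(sprintf("bad magic %d in label file (expected 2049)", magic2),
         call. = FALSE)
  }
  nl <- readBin(con2, integer(), 1L, size = 4L, endian = "big")
  if (nl != n) {
    stop(sprintf("label count %d does not match image count %d", nl, n),
         call. = FALSE)
  }
  labs <- as.integer(readBin(con2, "raw", nl))
  ## IDX rows are stored row-major (row, then column)
  images <- aperm(array(as.integer(px) / 255, c(28L, 28L, n)), c(3L, 2L, 1L))
  list(images = images, labels = labs)
}

#' Write an image/label pair in IDX format
#'
#' The writer mirrors [read_idx()] and exists mainly so tests and exports
#' can round-trip small corpora.
#'
#' @param images `N x 28 x 28` array in `[0, 1]`.
#' @param labels Integer labels, length `N`.
#' @param images_path,labels_path Output paths.
#' @return `invisible(NULL)`.
#' @export
write_idx <- function(images, labels, images_path, labels_path) {
  n <- dim(images)[1L]
  stopifnot(length(labels) == n, all(dim(images)[2:3] == 28L))
  con <- file(images_path, "wb")
  writeBin(c(2051L, n, 28L, 28L), con, size = 4L, endian = "big")
  px <- aperm(images, c(3L, 2L, 1L))   # back to row-major per image
  writeBin(as.raw(round(as.vector(px) * 255)), con)
  close(con)
  con2 <- file(labels_path, "wb")
  writeBin(c(2049L, n), con2, size = 4L, endian = "big")
  writeBin(as.raw(as.integer(labels)), con2)
  close(con2)
  invisible(NULL)
}

#' Intra-/inter-class feature distance report
#'
#' Summarizes the Euclidean distance distributions between feature vectors
#' of same-class and different-class image pairs, together with the
#' calibrated distance threshold (see [calibrate_t1()]). Supports the choice
#' of T1 for corpora other than MNIST.
#'
#' @param images `N x 28 x 28` array.
#' @param labels Integer labels.
#' @param feature_model Trained [feature_extractor].
#' @param n_pairs Random pairs sampled (default 20000).
#' @param seed Sampling seed.
#' @return List with `intra_mean`, `inter_mean`, `intra_quartiles`,
#'   `inter_quartiles`, `t1` and the sample sizes.
#' @export
corpus_confusability_report <- function(images, labels, feature_model,
                                        n_pairs = 20000L, seed = 1L) {
  FT <- extract_features(feature_model, images)
  labels <- as.integer(labels)
  with_seed(seed, {
    i <- sample.int(nrow(FT), n_pairs, replace = TRUE)
    j <- sample.int(nrow(FT), n_pairs, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    d <- sqrt(rowSums((FT[i, , drop = FALSE] - FT[j, , drop = FALSE])^2))
    same <- labels[i] == labels[j]
    q <- function(x) if (length(x)) quantile(x, c(0.25, 0.5, 0.75)) else
      setNames(rep(NA_real_, 3L), c("25%", "50%", "75%"))
    list(intra_mean = if (any(same)) mean(d[same]) else NA_real_,
         inter_mean = if (any(!same)) mean(d[!same]) else NA_real_,
         intra_quartiles = q(d[same]),
         inter_quartiles = q(d[!same]),
         t1 = as.numeric(quantile(d, 0.3)),
         n_intra = sum(same), n_inter = sum(!same))
  })
}
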