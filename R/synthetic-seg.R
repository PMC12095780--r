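# Synthetic endoscopy-like scenes: a smooth reddish background gradient with
# band-limited noise texture, one or more elliptical lesions with distinct
# texture and intensity, and small specular highlight disks. The mask is the
# union of the lesion ellipses. Deliberately minimal realism: enough
# structure for a small network to learn, cheap enough for routine testing.

#' Parameters of the synthetic segmentation scene generator
#'
#' @param n_images Number of image/mask pairs.
#' @param size Square image size in pixels (>= 32).
#' @param lesion_count_range Inclusive range of lesions per image.
#' @param lesion_axis_range Semi-axis range in pixels; defaults to
#'   `c(size/8, size/4)`. Axes must fit inside the image.
#' @param texture_scale Grid spacing (pixels) of the band-limited background
#'   noise; larger values give coarser texture.
#' @param highlight_count Specular highlight disks per image.
#' @param seed Integer seed; one global seed fans out to per-image sub-seeds
#'   through a counter so any subset regenerates identically.
#' @return A `seg_scene_params` object.
#' @export
seg_scene_params <- function(n_images = 10L, size = 64L,
                             lesion_count_range = c(1L, 3L),
                             lesion_axis_range = NULL,
                             texture_scale = 8L, highlight_count = 2L,
                             seed = 1L) {
  size <- as.integer(size)
  if (size < 32L) abort("invalid params: `size` must be >= 32 pixels")
  if (is.null(lesion_axis_range)) {
    lesion_axis_range <- c(size / 8, size / 4)
  }
  if (max(lesion_axis_range) * 2 > size) {
    abort("invalid params: lesion axes must fit inside the image")
  }
  if (lesion_count_range[1] < 0L) abort("invalid params: lesion counts must be >= 0")
  structure(
    list(n_images = as.integer(n_images), size = size,
         lesion_count_range = as.integer(lesion_count_range),
         lesion_axis_range = lesion_axis_range,
         texture_scale = as.integer(texture_scale),
         highlight_count = as.integer(highlight_count),
         seed = as.integer(seed)),
    class = "seg_scene_params"
  )
}

# counter-based sub-seed: reproducible per image independent of order
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i * 7919) %% 2147483647)
}

# smooth noise field: coarse Gaussian grid, bilinearly upsampled
smooth_noise <- function(size, scale) {
  g <- max(2L, ceiling(size / scale))
  coarse <- matrix(rnorm(g * g), g, g)
  resize_bilinear(coarse, size, size)
}

ellipse_mask <- function(size, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one synthetic scene
#'
#' @param params A [seg_scene_params()].
#' @param i Image index (1-based); drives the per-image sub-seed.
#' @return List with `image` (`size x size x 3`, values in `[0, 1]`) and
#'   `mask` (`size x size` binary matrix).
#' @export
gen_seg_scene <- function(params, i = 1L) {
  stopifnot(inherits(params, "seg_scene_params"))
  s <- params$size
  with_seed(sub_seed(params$seed, i), {
    # reddish background: directional gradient + band-limited texture
    ang <- runif(1, 0, 2 * pi)
    gx <- matrix(rep(seq_len(s) / s, each = s), s, s)
    gy <- matrix(rep(seq_len(s) / s, times = s), s, s)
    grad <- (cos(ang) * gx + sin(ang) * gy) * runif(1, 0.1, 0.25)
    tex <- smooth_noise(s, params$texture_scale) * 0.05
    r <- 0.55 + grad + tex
    g <- 0.25 + 0.6 * grad + tex
    b <- 0.20 + 0.5 * grad + tex
    mask <- matrix(FALSE, s, s)
    k <- if (params$lesion_count_range[1] == params$lesion_count_range[2]) {
      params$lesion_count_range[1]
    } else {
      sample(params$lesion_count_range[1]:params$lesion_count_range[2], 1)
    }
    for (les in seq_len(k)) {
      a <- runif(1, params$lesion_axis_range[1], params$lesion_axis_range[2])
      bb <- runif(1, params$lesion_axis_range[1], params$lesion_axis_range[2])
      cx <- runif(1, max(a, bb) + 1, s - max(a, bb) - 1)
      cy <- runif(1, max(a, bb) + 1, s - max(a, bb) - 1)
      th <- runif(1, 0, pi)
      em <- ellipse_mask(s, cx, cy, a, bb, th)
      # lesion: distinct brightness shift and its own fine texture
      shift <- sample(c(-1, 1), 1) * runif(1, 0.15, 0.3)
      ltex <- smooth_noise(s, max(2L, params$texture_scale %/% 2L)) * 0.06
      r[em] <- r[em] + shift + ltex[em]
      g[em] <- g[em] + 0.8 * shift + ltex[em]
      b[em] <- b[em] + 0.5 * shift + ltex[em]
      mask <- mask | em
    }
    for (h in seq_len(params$highlight_count)) {
      hr <- runif(1, 1.5, max(2, s / 24))
      hx <- runif(1, hr + 1, s - hr - 1)
      hy <- runif(1, hr + 1, s - hr - 1)
      hm <- ellipse_mask(s, hx, hy, hr, hr, 0)
      r[hm] <- 0.98; g[hm] <- 0.98; b[hm] <- 0.95
    }
    img <- array(c(r, g, b), dim = c(s, s, 3))
    img[img < 0] <- 0
    img[img > 1] <- 1
    list(image = img, mask = mask * 1L)
  })
}

#' Generate an in-memory synthetic segmentation dataset
#'
#' @param params A [seg_scene_params()].
#' @return List with `images` (`size x size x 3 x n`) and `masks`
#'   (`size x size x 1 x n`), the format consumed by
#'   [train_segmentation()].
#' @export
gen_seg_arrays <- function(params) {
  stopifnot(inherits(params, "seg_scene_params"))
  s <- params$size
  n <- params$n_images
  images <- array(0, c(s, s, 3L, n))
  masks <- array(0, c(s, s, 1L, n))
  for (i in seq_len(n)) {
    scene <- gen_seg_scene(params, i)
    images[, , , i] <- scene$image
    masks[, , 1, i] <- scene$mask
  }
  list(images = images, masks = masks)
}

#' Write a synthetic segmentation dataset to disk
#'
#' Produces the Kvasir-SEG-style layout: `images/img_0001.png`,
#' `masks/img_0001.png`, plus a `manifest.json` recording every generator
#' parameter. Byte-identical across runs with equal parameters.
#'
#' @param params A [seg_scene_params()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a tibble with columns `id`, `image`, `mask`.
#' @export
gen_seg_dataset <- function(params, dir) {
  stopifnot(inherits(params, "seg_scene_params"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("img_%04d", seq_len(params$n_images))
  for (i in seq_len(params$n_images)) {
    scene <- gen_seg_scene(params, i)
    write_image(scene$image, file.path(dir, "images", paste0(ids[i], ".png")))
    write_image(array(scene$mask, dim = c(params$size, params$size)),
                file.path(dir, "masks", paste0(ids[i], ".png")))
  }
  jsonlite::write_json(unclass(params), file.path(dir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(tibble(
    id = ids,
    image = file.path(dir, "images", paste0(ids, ".png")),
    mask = file.path(dir, "masks", paste0(ids, ".png"))
  ))
}
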