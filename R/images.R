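# Image IO and resampling. PNG through the png package; JPEG through
# EBImage when available. Images are H x W x 3 numeric arrays in [0, 1];
# masks are H x W in {0, 1}.

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      abort("reading JPEG requires the EBImage package")
    }
    # EBImage uses x-y order; transpose back to row-major H x W
    aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
  } else {
    abort(sprintf("unsupported image format: .%s (%s)", ext, path))
  }
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

read_mask <- function(path, level = 127 / 255) {
  img <- read_image(path)
  m <- if (length(dim(img)) == 3L) img[, , 1] else img
  (m > level) * 1L
}

write_image <- function(img, path) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

# Bilinear resampling of an H x W (x C) array to (out_h, out_w); used for
# images. Masks go through resize_nearest and are re-binarized by callers.
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  had_ch <- length(d) == 3L
  if (!had_ch) dim(img) <- c(d, 1L)
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  # align centers: map output pixel centers into input coordinates
  yi <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
  xi <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
  y0 <- pmin(pmax(floor(yi - 0.5) + 0.5, 0.5), H - 0.5)
  x0 <- pmin(pmax(floor(xi - 0.5) + 0.5, 0.5), W - 0.5)
  fy <- pmin(pmax(yi - y0, 0), 1)
  fx <- pmin(pmax(xi - x0, 0), 1)
  iy0 <- pmin(pmax(ceiling(y0), 1L), H); iy1 <- pmin(iy0 + 1L, H)
  ix0 <- pmin(pmax(ceiling(x0), 1L), W); ix1 <- pmin(ix0 + 1L, W)
  out <- array(0, c(out_h, out_w, C))
  wy0 <- 1 - fy; wx0 <- 1 - fx
  for (c in seq_len(C)) {
    ch <- img[, , c]
    a <- ch[iy0, ix0, drop = FALSE] * (wy0 %o% wx0) +
      ch[iy1, ix0, drop = FALSE] * (fy %o% wx0) +
      ch[iy0, ix1, drop = FALSE] * (wy0 %o% fx) +
      ch[iy1, ix1, drop = FALSE] * (fy %o% fx)
    out[, , c] <- a
  }
  if (had_ch) out else out[, , 1]
}

resize_nearest <- function(img, out_h, out_w) {
  d <- dim(img)
  had_ch <- length(d) == 3L
  if (!had_ch) dim(img) <- c(d, 1L)
  H <- dim(img)[1]; W <- dim(img)[2]
  iy <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * H / out_h), 1L), H)
  ix <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * W / out_w), 1L), W)
  out <- img[iy, ix, , drop = FALSE]
  if (had_ch) out else out[, , 1]
}
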