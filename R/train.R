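# Training harness for the segmentation network: dataset splitting, the
# Adam + binary-cross-entropy training loop, and a reduce-on-plateau
# learning-rate schedule.

#' Training protocol for segmentation
#'
#' Defaults follow the study protocol: Adam starting at learning rate 0.01,
#' reduce-on-plateau down to a floor of 1e-5, batch size 16, 100 epochs,
#' 256x256 inputs and an 80/10/10 train/test/validation split. The plateau
#' factor (0.5) and patience (5 epochs, monitored on validation loss) are
#' declared defaults of this implementation.
#'
#' @param lr_init,lr_min Initial and floor learning rates.
#' @param factor,patience Plateau schedule: multiply the rate by `factor`
#'   after `patience` epochs without validation-loss improvement.
#' @param batch Mini-batch size.
#' @param epochs Number of epochs.
#' @param input Input size `(H, W)` in pixels.
#' @param split Train/test/validation fractions; must sum to 1.
#' @param seed Integer seed governing shuffling and splitting.
#' @return A `train_protocol` object.
#' @export
train_protocol <- function(lr_init = 0.01, lr_min = 1e-5, factor = 0.5,
                           patience = 5L, batch = 16L, epochs = 100L,
                           input = c(256L, 256L), split = c(0.8, 0.1, 0.1),
                           seed = 42L) {
  if (!(lr_min < lr_init)) abort("invalid protocol: lr_min must be < lr_init")
  if (batch < 1L) abort("invalid protocol: batch must be >= 1")
  if (abs(sum(split) - 1) > 1e-9) abort("invalid protocol: split fractions must sum to 1")
  if (epochs < 0L) abort("invalid protocol: epochs must be >= 0")
  structure(
    list(optimizer = "adam", lr_init = lr_init, lr_min = lr_min,
         factor = factor, patience = as.integer(patience),
         batch = as.integer(batch), epochs = as.integer(epochs),
         input = as.integer(input), split = split, seed = as.integer(seed)),
    class = "train_protocol"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Split sample ids into train / test / validation sets
#'
#' Test and validation sizes are `round(n * fraction)`; the remainder goes
#' to train, so 1000 items at fractions (0.8, 0.1, 0.1) give 800/100/100.
#' The shuffle is deterministic under `seed` and the three sets partition
#' the input exactly.
#'
#' @param items Vector of sample identifiers.
#' @param fractions Train/test/validation fractions summing to 1.
#' @param seed Integer seed.
#' @return Named list of three disjoint vectors: `train`, `test`, `val`.
#' @examples
#' lengths(split_dataset(1:1000, c(0.8, 0.1, 0.1), seed = 1))
#' @export
split_dataset <- function(items, fractions = c(0.8, 0.1, 0.1), seed = 42L) {
  if (length(items) == 0L) abort("split_dataset needs a non-empty item list")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9) {
    abort("fractions must be three numbers summing to 1")
  }
  n <- length(items)
  n_test <- round(n * fractions[2])
  n_val <- round(n * fractions[3])
  n_train <- n - n_test - n_val
  perm <- with_seed(seed, sample.int(n))
  list(
    train = items[perm[seq_len(n_train)]],
    test = items[perm[n_train + seq_len(n_test)]],
    val = items[perm[n_train + n_test + seq_len(n_val)]]
  )
}

#' Load an image/mask dataset from disk
#'
#' Expects the Kvasir-SEG-style layout: `images/*.png|jpg` and
#' `masks/*.png` with identical file stems. Masks are binarized at
#' intensity 127/255. When `size` is given, images are resampled
#' bilinearly and masks by nearest neighbor, then re-binarized.
#'
#' @param dir Dataset root containing `images/` and `masks/`.
#' @param size Optional target size `(H, W)`.
#' @return List with `images` (`H x W x 3 x N`), `masks` (`H x W x 1 x N`)
#'   and `ids` (file stems).
#' @export
load_seg_dataset <- function(dir, size = NULL) {
  img_files <- sort(list.files(file.path(dir, "images"), full.names = TRUE,
                               pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE))
  if (length(img_files) == 0L) abort(sprintf("no images under %s/images", dir))
  stems <- tools::file_path_sans_ext(basename(img_files))
  mask_files <- file.path(dir, "masks", paste0(stems, ".png"))
  missing <- !file.exists(mask_files)
  if (any(missing)) {
    abort(sprintf("missing masks for: %s",
                  paste(head(stems[missing], 5), collapse = ", ")))
  }
  imgs <- lapply(img_files, read_image)
  msks <- lapply(mask_files, read_mask)
  if (!is.null(size)) {
    imgs <- lapply(imgs, resize_bilinear, out_h = size[1], out_w = size[2])
    msks <- lapply(msks, function(m) {
      (resize_nearest(m, size[1], size[2]) > 0.5) * 1L
    })
  }
  d <- dim(imgs[[1]])
  images <- array(unlist(imgs), dim = c(d[1], d[2], 3L, length(imgs)))
  masks <- array(unlist(msks), dim = c(d[1], d[2], 1L, length(msks)))
  list(images = images, masks = masks, ids = stems)
}

batch_counts <- function(prob, truth, threshold = 0.5) {
  p <- prob >= threshold
  t <- truth > 0.5
  c(tp = sum(p & t), fp = sum(p & !t), tn = sum(!p & !t), fn = sum(!p & t))
}

counts_metrics <- function(cn) {
  tp <- cn["tp"]; fp <- cn["fp"]; tn <- cn["tn"]; fn <- cn["fn"]
  c(dice = unname(if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_),
    jaccard = unname(if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_),
    acc = unname((tp + tn) / (tp + tn + fp + fn)))
}

#' Train a segmentation model
#'
#' Mini-batch optimization of binary cross-entropy with Adam. The learning
#' rate is multiplied by `protocol$factor` when the monitored loss
#' (validation loss if validation data is supplied, else training loss)
#' fails to improve for `protocol$patience` consecutive epochs, floored at
#' `protocol$lr_min`. Per-epoch pixel metrics (Dice, Jaccard, accuracy) are
#' pooled over the epoch's batches at threshold 0.5.
#'
#' @param model A [build_gisegnet()] model; updated in place and returned.
#' @param data List with `images` (`H x W x 3 x N`) and `masks`
#'   (`H x W x 1 x N`), e.g. from [load_seg_dataset()] or
#'   [gen_seg_arrays()].
#' @param protocol A [train_protocol()].
#' @param val Optional validation data in the same format.
#' @param verbose Print one line per epoch.
#' @return The model, with a `history` tibble attached (class `gi_history`):
#'   one row per epoch with `loss`, `dice`, `jaccard`, `acc`, their `val_`
#'   counterparts (NA without validation data) and the learning rate.
#' @export
train_segmentation <- function(model, data, protocol = train_protocol(),
                               val = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "gisegnet_model"), inherits(protocol, "train_protocol"))
  n <- dim(data$images)[4]
  opt <- adam_optimizer(model$params, lr = protocol$lr_init)
  lr <- protocol$lr_init
  best <- Inf
  stale <- 0L
  hist <- vector("list", protocol$epochs)
  if (protocol$epochs > 0L) with_seed(protocol$seed, {
    for (epoch in seq_len(protocol$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = protocol$batch)
      epoch_loss <- 0
      cn <- c(tp = 0, fp = 0, tn = 0, fn = 0)
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + protocol$batch - 1L, n)]
        xb <- data$images[, , , idx, drop = FALSE]
        yb <- data$masks[, , , idx, drop = FALSE]
        ag_zero_grad(model$params)
        logits <- model$forward_logits(ag_const(xb), training = TRUE)
        loss <- ag_bce_logits(logits, yb)
        if (!is.finite(loss$value)) {
          abort(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi))
        }
        ag_backward(loss)
        opt$lr <- lr
        adam_step(opt)
        epoch_loss <- epoch_loss + loss$value * length(idx)
        cn <- cn + batch_counts(1 / (1 + exp(-logits$value)), yb)
      }
      epoch_loss <- epoch_loss / n
      m <- counts_metrics(cn)
      vrow <- c(loss = NA_real_, dice = NA_real_, jaccard = NA_real_, acc = NA_real_)
      if (!is.null(val)) {
        vlogits <- model$forward_logits(ag_const(val$images), training = FALSE)
        vloss <- mean(pmax(vlogits$value, 0) - vlogits$value * val$masks +
                        log1p(exp(-abs(vlogits$value))))
        vcn <- batch_counts(1 / (1 + exp(-vlogits$value)), val$masks)
        vrow <- c(loss = vloss, counts_metrics(vcn))
      }
      monitored <- if (!is.null(val)) vrow["loss"] else epoch_loss
      if (monitored < best - 1e-12) {
        best <- monitored
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= protocol$patience) {
          lr <- max(lr * protocol$factor, protocol$lr_min)
          stale <- 0L
        }
      }
      hist[[epoch]] <- tibble(
        epoch = epoch, loss = epoch_loss, val_loss = unname(vrow["loss"]),
        dice = m["dice"], val_dice = unname(vrow["dice"]),
        jaccard = m["jaccard"], val_jaccard = unname(vrow["jaccard"]),
        acc = m["acc"], val_acc = unname(vrow["acc"]), lr = lr
      )
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  dice %.4f  lr %.5f",
                        epoch, epoch_loss, m["dice"], lr))
      }
    }
  })
  history <- if (protocol$epochs > 0L) dplyr::bind_rows(hist) else {
    tibble(epoch = integer(), loss = numeric(), val_loss = numeric(),
           dice = numeric(), val_dice = numeric(), jaccard = numeric(),
           val_jaccard = numeric(), acc = numeric(), val_acc = numeric(),
           lr = numeric())
  }
  class(history) <- c("gi_history", class(history))
  model$history <- history
  model
}

#' Write a training history to CSV and JSON
#'
#' @param history A `gi_history` tibble from [train_segmentation()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the history.
#' @export
write_history <- function(history, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(history, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(history, json_path, dataframe = "columns", digits = NA)
  }
  invisible(history)
}
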