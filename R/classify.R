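# Hybrid classification pipeline: image preprocessing, pluggable feature
# extractors (with deterministic stub backbones for offline use), columnwise
# feature fusion, minimum-redundancy maximum-relevance (mRMR) ranking, and a
# cubic-kernel one-vs-one SVM with stratified k-fold evaluation.

#' The eight gastrointestinal finding classes
#' @export
gi_class_names <- c("dyed-lifted-polyps", "dyed-resection-margins",
                    "esophagitis", "normal-cecum", "normal-pylorus",
                    "normal-z-line", "polyps", "ulcerative-colitis")

# ---- extractor contracts and stub backbones ---------------------------------

extractor_dims <- c(deit3_base_p16 = 768L, maxvit_base = 768L,
                    swin_base_p4w7 = 1024L, vit_base_p16 = 768L)

#' Contract of a feature extractor
#'
#' Fixes the input size (224x224x3) and output dimension of each supported
#' backbone: 768 features for deit3_base_p16, maxvit_base and vit_base_p16;
#' 1024 for swin_base_p4w7.
#'
#' @param name One of `"deit3_base_p16"`, `"maxvit_base"`, `"swin_base_p4w7"`,
#'   `"vit_base_p16"`.
#' @return An `extractor_contract` object with `name`, `input`, `out_dim`.
#' @export
extractor_contract <- function(name) {
  name <- match.arg(name, names(extractor_dims))
  structure(list(name = name, input = c(224L, 224L, 3L),
                 out_dim = extractor_dims[[name]]),
            class = "extractor_contract")
}

#' Deterministic stub backbone honouring an extractor contract
#'
#' Pools the image to a 16x16x3 grid and projects the flattened 768-vector
#' through a fixed seeded random map to `out_dim` features with a tanh
#' nonlinearity. Purely a stand-in with the correct dimensionality and
#' determinism, so the pipeline runs without pretrained weights; any real
#' backbone with matching `out_dim` can be plugged in instead.
#'
#' @param contract An [extractor_contract()].
#' @param seed Seed of the fixed projection.
#' @return A `gi_backbone` with elements `contract`, `forward(images)` and a
#'   trainable linear `head` used by [fine_tune()].
#' @export
stub_backbone <- function(contract, seed = 7L) {
  stopifnot(inherits(contract, "extractor_contract"))
  d_in <- 16L * 16L * 3L
  proj <- with_seed(sub_seed(seed, match(contract$name, names(extractor_dims))), {
    matrix(rnorm(contract$out_dim * d_in, sd = 1 / sqrt(d_in)),
           contract$out_dim, d_in)
  })
  backbone <- list(
    contract = contract,
    forward = function(images) {
      feats <- t(vapply(images, function(img) {
        small <- resize_bilinear(img, 16L, 16L)
        as.vector(tanh(proj %*% as.vector(small)))
      }, numeric(contract$out_dim)))
      if (length(images) == 0L) feats <- matrix(0, 0L, contract$out_dim)
      feats
    },
    head = NULL,
    loss_history = numeric()
  )
  class(backbone) <- "gi_backbone"
  backbone
}

# ---- preprocessing ----------------------------------------------------------

#' Preprocess images for classification
#'
#' Training mode applies a seeded random resized crop (area scale 0.5-1,
#' aspect 3/4-4/3) followed by a horizontal flip with probability 0.5; eval
#' mode applies a deterministic center resize-crop. Output values stay in
#' `[0, 1]`.
#'
#' @param paths Character vector of image files, or a list of `H x W x 3`
#'   arrays.
#' @param size Target square size (default 224).
#' @param train_mode Apply random augmentation.
#' @param seed Seed for the augmentation draws.
#' @return List of `size x size x 3` arrays. Unreadable files are skipped
#'   with a warning; if more than 10% are unreadable the run fails.
#' @export
preprocess_images <- function(paths, size = 224L, train_mode = FALSE,
                              seed = 1L) {
  imgs <- if (is.character(paths)) {
    loaded <- lapply(paths, function(p) tryCatch(read_image(p), error = function(e) NULL))
    bad <- vapply(loaded, is.null, logical(1))
    if (any(bad)) {
      warning(sprintf("skipped %d unreadable file(s): %s", sum(bad),
                      paste(head(paths[bad], 5), collapse = ", ")))
      if (mean(bad) > 0.1) {
        abort(sprintf("%.0f%% of inputs unreadable; aborting", 100 * mean(bad)))
      }
    }
    loaded[!bad]
  } else {
    paths
  }
  with_seed(seed, lapply(imgs, function(img) {
    H <- dim(img)[1]; W <- dim(img)[2]
    if (train_mode) {
      # random resized crop: sample an area fraction and aspect ratio
      for (att in 1:10) {
        frac <- runif(1, 0.5, 1)
        ratio <- exp(runif(1, log(3 / 4), log(4 / 3)))
        ch <- round(sqrt(H * W * frac / ratio))
        cw <- round(ch * ratio)
        if (ch <= H && cw <= W) break
        ch <- H; cw <- W
      }
      top <- sample.int(H - ch + 1L, 1)
      left <- sample.int(W - cw + 1L, 1)
      crop <- img[top:(top + ch - 1L), left:(left + cw - 1L), , drop = FALSE]
      out <- resize_bilinear(crop, size, size)
      if (runif(1) < 0.5) out <- out[, rev(seq_len(size)), , drop = FALSE]
      out
    } else {
      # center resize-crop: scale the short side to `size`, crop the middle
      sc <- size / min(H, W)
      rh <- max(size, round(H * sc)); rw <- max(size, round(W * sc))
      res <- resize_bilinear(img, rh, rw)
      top <- (rh - size) %/% 2L; left <- (rw - size) %/% 2L
      res[top + seq_len(size), left + seq_len(size), , drop = FALSE]
    }
  }))
}

# ---- extraction and fine-tuning ---------------------------------------------

#' Extract features from a batch of images
#'
#' @param contract An [extractor_contract()].
#' @param images List of preprocessed `H x W x 3` arrays.
#' @param backbone A `gi_backbone`; defaults to the seeded stub for the
#'   contract. Its output dimension must match the contract.
#' @param labels Optional integer labels attached as the `label` column.
#' @return A feature tibble (`n x out_dim` plus optional `label`), columns
#'   tagged with the extractor name as their origin.
#' @export
extract_features <- function(contract, images, backbone = NULL, labels = NULL) {
  stopifnot(inherits(contract, "extractor_contract"))
  backbone <- backbone %||% stub_backbone(contract)
  feats <- backbone$forward(images)
  if (ncol(feats) != contract$out_dim) {
    abort(sprintf("backbone produced %d features but the %s contract requires %d",
                  ncol(feats), contract$name, contract$out_dim))
  }
  fm <- feature_matrix(feats,
                       if (is.null(labels)) rep(NA_integer_, nrow(feats)) else labels,
                       origin = rep(contract$name, contract$out_dim))
  if (is.null(labels)) fm$label <- NULL
  fm
}

#' Fine-tune a backbone's linear classifier head
#'
#' Trains a linear softmax head on the backbone's features by plain
#' mini-batch gradient descent on cross-entropy. Defaults follow the
#' classification protocol: learning rate 1e-5, 20 epochs, mini-batch 2.
#' The feature map itself is frozen (the stub backbones have no trainable
#' body); the updated head and its loss history are returned on the
#' backbone.
#'
#' @param backbone A `gi_backbone`.
#' @param images List of preprocessed images.
#' @param labels Integer class labels (0-based).
#' @param lr,epochs,batch Optimization settings.
#' @param seed Shuffling seed.
#' @return The backbone with `head` (list `W`, `b`) and `loss_history`
#'   (one mean cross-entropy value per epoch, the first computed before any
#'   update).
#' @export
fine_tune <- function(backbone, images, labels, lr = 1e-5, epochs = 20L,
                      batch = 2L, seed = 1L) {
  stopifnot(inherits(backbone, "gi_backbone"))
  if (epochs == 0L) return(backbone)
  X <- backbone$forward(images)
  y <- as.integer(labels)
  classes <- sort(unique(y))
  K <- length(classes)
  n <- nrow(X)
  d <- ncol(X)
  Wh <- backbone$head$W %||% matrix(0, K, d)
  bh <- backbone$head$b %||% numeric(K)
  ce <- function(W, b) {
    z <- X %*% t(W) + matrix(b, n, K, byrow = TRUE)
    z <- z - apply(z, 1, max)
    p <- exp(z) / rowSums(exp(z))
    -mean(log(pmax(p[cbind(seq_len(n), match(y, classes))], 1e-12)))
  }
  losses <- numeric(0)
  if (epochs > 0L) with_seed(seed, {
    for (ep in seq_len(epochs)) {
      losses <- c(losses, ce(Wh, bh))
      perm <- sample.int(n)
      for (start in seq(1L, n, by = batch)) {
        idx <- perm[start:min(start + batch - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        z <- Xb %*% t(Wh) + matrix(bh, length(idx), K, byrow = TRUE)
        z <- z - apply(z, 1, max)
        p <- exp(z) / rowSums(exp(z))
        t_onehot <- matrix(0, length(idx), K)
        t_onehot[cbind(seq_along(idx), match(y[idx], classes))] <- 1
        gz <- (p - t_onehot) / length(idx)
        if (any(!is.finite(gz))) abort(sprintf("non-finite loss in fine_tune at epoch %d", ep))
        Wh <- Wh - lr * t(gz) %*% Xb
        bh <- bh - lr * colSums(gz)
      }
    }
    losses <- c(losses, ce(Wh, bh))
  })
  backbone$head <- list(W = Wh, b = bh, classes = classes)
  backbone$loss_history <- losses
  backbone
}

# ---- fusion -----------------------------------------------------------------

#' Fuse feature matrices by columnwise concatenation
#'
#' All inputs must have the same row count, identical label vectors and
#' identical sample order; a label mismatch is a hard error, preventing
#' silent sample misalignment. Per-column origin tags are preserved, so
#' [slice_by_origin()] recovers the original matrices exactly.
#'
#' @param ... Feature tibbles, or a single list of them.
#' @return A fused feature tibble; `ncol - 1` equals the sum of input
#'   feature dimensions.
#' @examples
#' \dontrun{
#' fused <- fuse(deit3_features, vit_features)  # 768 + 768 = 1536 columns
#' }
#' @export
fuse <- function(...) {
  fms <- list(...)
  if (length(fms) == 1L && !inherits(fms[[1]], "data.frame")) fms <- fms[[1]]
  stopifnot(length(fms) >= 1L)
  if (length(fms) == 1L) return(fms[[1]])
  y0 <- fms[[1]]$label
  for (fm in fms[-1]) {
    if (nrow(fm) != nrow(fms[[1]])) abort("fuse: row counts differ")
    if (!identical(as.integer(fm$label), as.integer(y0))) {
      abort("fuse: label vectors differ; refusing to misalign samples")
    }
  }
  X <- do.call(cbind, lapply(fms, feature_values))
  origin <- unlist(lapply(fms, function(fm) attr(fm, "origin")), use.names = FALSE)
  feature_matrix(X, y0, origin = origin)
}

#' Recover one extractor's columns from a fused matrix
#'
#' @param fm A fused feature tibble.
#' @param name Origin tag to select.
#' @return The feature tibble restricted to that origin.
#' @export
slice_by_origin <- function(fm, name) {
  origin <- attr(fm, "origin")
  keep <- which(origin == name)
  if (length(keep) == 0L) abort(sprintf("no columns with origin '%s'", name))
  feature_matrix(feature_values(fm)[, keep, drop = FALSE], fm$label,
                 origin = origin[keep])
}

# ---- mRMR -------------------------------------------------------------------

# equal-frequency binning into `bins` levels (integer codes 1..bins)
ef_bin <- function(x, bins = 10L) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        type = 1, names = FALSE))
  if (length(qs) <= 2L) return(rep(1L, length(x)))
  cut(x, breaks = qs, labels = FALSE, include.lowest = TRUE)
}

# mutual information (nats) between two integer codes
mi_disc <- function(a, b, na, nb) {
  joint <- tabulate(a + na * (b - 1L), nbins = na * nb)
  joint <- joint / length(a)
  pa <- tabulate(a, nbins = na) / length(a)
  pb <- tabulate(b, nbins = nb) / length(b)
  pij <- matrix(joint, na, nb)
  pos <- pij > 0
  sum(pij[pos] * log(pij[pos] / (pa[row(pij)[pos]] * pb[col(pij)[pos]])))
}

#' Rank features by minimum redundancy, maximum relevance
#'
#' Greedy forward selection with the difference criterion: the first pick
#' maximizes the mutual information `I(f; y)` with the label, and each
#' subsequent pick maximizes `I(f; y) - mean_{s in S} I(f; f_s)` over the
#' already-selected set `S`. Continuous features are discretized into 10
#' equal-frequency bins before estimating mutual information; labels are
#' used as-is. Ties break toward the lowest column index, making rankings
#' reproducible. A constant column has zero relevance and is only ever
#' selected last.
#'
#' @param fm A feature tibble with a `label` column.
#' @param k Subset size (`<=` number of feature columns).
#' @param bins Discretization bins (default 10).
#' @return A `mrmr_ranking`: list with `ranked_idx` (column indices in
#'   selection order), `scores` (the criterion value at each pick) and `k`.
#' @export
mrmr_rank <- function(fm, k, bins = 10L) {
  X <- feature_values(fm)
  y <- as.integer(fm$label)
  d <- ncol(X)
  if (k > d) abort(sprintf("k = %d exceeds the %d available features", k, d))
  B <- matrix(0L, nrow(X), d)
  for (j in seq_len(d)) B[, j] <- ef_bin(X[, j], bins)
  ycode <- match(y, sort(unique(y)))
  ny <- max(ycode)
  rel <- vapply(seq_len(d), function(j) mi_disc(B[, j], ycode, bins, ny), numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(d)  # sum of I(f_j; f_s) over selected s
  avail <- rep(TRUE, d)
  for (step in seq_len(k)) {
    crit <- rel - if (step == 1L) 0 else red_sum / length(selected)
    crit[!avail] <- -Inf
    pick <- which.max(crit)  # which.max takes the first (lowest index) on ties
    selected <- c(selected, pick)
    scores <- c(scores, crit[pick])
    avail[pick] <- FALSE
    if (step < k) {
      for (j in which(avail)) {
        red_sum[j] <- red_sum[j] + mi_disc(B[, j], B[, pick], bins, bins)
      }
    }
  }
  structure(list(ranked_idx = selected, scores = scores, k = as.integer(k)),
            class = "mrmr_ranking")
}

#' Keep the top-k columns of a ranking
#'
#' @param fm The feature tibble the ranking was computed on.
#' @param ranking A [mrmr_rank()] result.
#' @param k Optional smaller prefix.
#' @return The reduced feature tibble (columns in original order).
#' @export
select_features <- function(fm, ranking, k = ranking$k) {
  idx <- sort(ranking$ranked_idx[seq_len(k)])
  origin <- attr(fm, "origin")
  feature_matrix(feature_values(fm)[, idx, drop = FALSE], fm$label,
                 origin = if (!is.null(origin)) origin[idx] else rep("unknown", length(idx)))
}

# ---- SVM --------------------------------------------------------------------

#' Cubic-kernel SVM settings
#'
#' Polynomial kernel of degree 3 ("cubic"), box constraint 1, one-vs-one
#' multiclass voting, automatic kernel scale (gamma set to
#' `1 / (d * mean variance)` of the standardized training features).
#'
#' @param degree Polynomial degree.
#' @param box_constraint Soft-margin cost `C`.
#' @param coef0 Kernel offset.
#' @return An `svm_params` object.
#' @export
svm_params <- function(degree = 3L, box_constraint = 1, coef0 = 1) {
  if (box_constraint <= 0) abort("box_constraint must be > 0")
  structure(list(degree = as.integer(degree), box_constraint = box_constraint,
                 coef0 = coef0), class = "svm_params")
}

# z-score using train statistics only; constant columns are left centered
standardize_train <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
}

#' Train a cubic SVM and predict test labels
#'
#' Features are standardized per column with statistics fitted on the
#' training rows only. Multiclass prediction uses one-vs-one voting over
#' all class pairs (the e1071 implementation of the soft-margin SVM is used
#' for the quadratic program).
#'
#' @param train Feature tibble with labels.
#' @param test Feature tibble (labels optional, ignored for prediction).
#' @param params An [svm_params()].
#' @return Integer vector of predicted labels, drawn from the training
#'   label set.
#' @export
svm_train_predict <- function(train, test, params = svm_params()) {
  Xtr <- feature_values(train)
  ytr <- as.integer(train$label)
  if (length(unique(ytr)) < 2L) abort("svm needs at least two classes in training data")
  Xte <- feature_values(test)
  z <- standardize_train(Xtr, Xte)
  gamma <- 1 / (ncol(Xtr) * max(mean(apply(z$train, 2, var)), 1e-12))
  fit <- e1071::svm(z$train, factor(ytr), kernel = "polynomial",
                    degree = params$degree, coef0 = params$coef0,
                    gamma = gamma, cost = params$box_constraint,
                    scale = FALSE)
  as.integer(as.character(predict(fit, z$test)))
}

# ---- cross-validation -------------------------------------------------------

# deterministic stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < folds) {
        abort(sprintf("class %s has %d members; need at least %d for %d-fold CV",
                      cls, length(idx), folds, folds))
      }
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}

#' Stratified k-fold cross-validated SVM accuracy
#'
#' @param fm Feature tibble with labels.
#' @param folds Number of folds (default 5).
#' @param params An [svm_params()].
#' @param seed Fold-assignment seed.
#' @return A `gi_crossval` object: `accuracy` (mean over folds),
#'   `fold_accuracy`, pooled `confusion` matrix (true x predicted) and
#'   `n`. Has [tidy()] and [glance()] methods.
#' @export
crossval_accuracy <- function(fm, folds = 5L, params = svm_params(),
                              seed = 1L) {
  y <- as.integer(fm$label)
  fold_id <- stratified_folds(y, folds, seed)
  classes <- sort(unique(y))
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, pred = classes))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fm[fold_id != f, ]
    te <- fm[fold_id == f, ]
    attr(tr, "origin") <- attr(fm, "origin")
    attr(te, "origin") <- attr(fm, "origin")
    pred <- svm_train_predict(tr, te, params)
    truth <- as.integer(te$label)
    fold_acc[f] <- mean(pred == truth)
    for (i in seq_along(pred)) {
      conf[match(truth[i], classes), match(pred[i], classes)] <-
        conf[match(truth[i], classes), match(pred[i], classes)] + 1L
    }
  }
  structure(list(accuracy = mean(fold_acc), fold_accuracy = fold_acc,
                 confusion = conf, folds = as.integer(folds), n = length(y),
                 params = params, seed = as.integer(seed)),
            class = "gi_crossval")
}

#' @export
print.gi_crossval <- function(x, ...) {
  cat(sprintf("<gi_crossval> %d-fold accuracy %.4f (folds: %s)\n",
              x$folds, x$accuracy,
              paste(formatC(x$fold_accuracy, digits = 3, format = "f"),
                    collapse = ", ")))
  invisible(x)
}

# ---- feature table IO -------------------------------------------------------

#' Write / read a feature table as CSV plus an origin sidecar
#'
#' The CSV has header `f_0001..f_dddd,label`; the sidecar JSON (same path
#' with extension `.origin.json`) records the per-column origin tags.
#'
#' @param fm Feature tibble.
#' @param path CSV path.
#' @return The reader returns the feature tibble; the writer returns `path`
#'   invisibly.
#' @export
write_features_csv <- function(fm, path) {
  write.csv(as.data.frame(fm), path, row.names = FALSE)
  origin <- attr(fm, "origin")
  if (!is.null(origin)) {
    jsonlite::write_json(origin, paste0(path, ".origin.json"))
  }
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  has_label <- "label" %in% names(df)
  X <- as.matrix(df[setdiff(names(df), "label")])
  origin_path <- paste0(path, ".origin.json")
  origin <- if (file.exists(origin_path)) {
    as.character(jsonlite::read_json(origin_path, simplifyVector = TRUE))
  } else rep("unknown", ncol(X))
  fm <- feature_matrix(X, if (has_label) df$label else rep(NA_integer_, nrow(X)),
                       origin = origin)
  if (!has_label) fm$label <- NULL
  fm
}
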