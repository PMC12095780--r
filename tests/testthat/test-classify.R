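test_that("eval preprocessing center-crops deterministically", {
  imgs <- list(array(runif(448 * 448 * 3), c(448, 448, 3)),
               array(runif(300 * 500 * 3), c(300, 500, 3)))
  out <- preprocess_images(imgs, size = 224)
  expect_equal(length(out), 2)
  for (o in out) expect_equal(dim(o), c(224, 224, 3))
  expect_equal(preprocess_images(imgs, size = 224), out)  # deterministic
})

test_that("train-mode augmentation is seeded and reproducible", {
  imgs <- tiny_images(3, size = 64, seed = 4)
  a <- preprocess_images(imgs, size = 32, train_mode = TRUE, seed = 11)
  b <- preprocess_images(imgs, size = 32, train_mode = TRUE, seed = 11)
  expect_identical(a, b)
  c <- preprocess_images(imgs, size = 32, train_mode = TRUE, seed = 12)
  expect_false(identical(a, c))
  expect_true(all(vapply(a, function(x) all(x >= 0 & x <= 1), logical(1))))
})

test_that("unreadable files are skipped with a warning, or fail the run", {
  dir <- tempfile("imgs"); dir.create(dir)
  good <- file.path(dir, sprintf("g%02d.png", 1:10))
  for (g in good) png::writePNG(array(runif(48), c(4, 4, 3)), g)
  bad <- file.path(dir, "bad.png")
  writeLines("not a png", bad)
  expect_warning(out <- preprocess_images(c(good, bad), size = 8), "skipped")
  expect_equal(length(out), 10)
  # more than 10% unreadable aborts
  expect_error(suppressWarnings(preprocess_images(c(good[1:2], bad), size = 8)),
               "unreadable")
  unlink(dir, recursive = TRUE)
})

test_that("extractor contracts pin the advertised output dimensions", {
  expect_equal(extractor_contract("deit3_base_p16")$out_dim, 768)
  expect_equal(extractor_contract("maxvit_base")$out_dim, 768)
  expect_equal(extractor_contract("swin_base_p4w7")$out_dim, 1024)
  expect_equal(extractor_contract("vit_base_p16")$out_dim, 768)
  expect_error(extractor_contract("resnet50"))
})

test_that("stub extraction yields contract-shaped deterministic features", {
  imgs <- tiny_images(5, size = 32)
  f_deit <- extract_features(extractor_contract("deit3_base_p16"), imgs)
  expect_equal(dim(feature_values(f_deit)), c(5, 768))
  f_swin <- extract_features(extractor_contract("swin_base_p4w7"), imgs[1:3])
  expect_equal(dim(feature_values(f_swin)), c(3, 1024))
  # empty batch: 0 x d, no error
  f0 <- extract_features(extractor_contract("vit_base_p16"), list())
  expect_equal(dim(feature_values(f0)), c(0, 768))
  # deterministic
  expect_identical(feature_values(f_deit),
                   feature_values(extract_features(extractor_contract("deit3_base_p16"), imgs)))
  # contract violation is a hard error
  bad <- stub_backbone(extractor_contract("swin_base_p4w7"))
  expect_error(extract_features(extractor_contract("deit3_base_p16"), imgs,
                                backbone = bad), "contract requires")
})

test_that("fine-tuning descends on a separable task and is reproducible", {
  imgs <- c(lapply(1:8, function(i) array(0.9, c(16, 16, 3))),
            lapply(1:8, function(i) array(0.1, c(16, 16, 3))))
  y <- rep(c(0L, 1L), each = 8)
  bb <- stub_backbone(extractor_contract("vit_base_p16"))
  # zero epochs: backbone untouched
  expect_identical(fine_tune(bb, imgs, y, epochs = 0L)$head, bb$head)
  ft <- fine_tune(bb, imgs, y, lr = 1e-2, epochs = 20L, batch = 2L, seed = 3)
  expect_lt(tail(ft$loss_history, 1), ft$loss_history[1])
  ft2 <- fine_tune(bb, imgs, y, lr = 1e-2, epochs = 20L, batch = 2L, seed = 3)
  expect_identical(ft$loss_history, ft2$loss_history)
  # the protocol's own tiny learning rate also never increases the loss
  ft3 <- fine_tune(bb, imgs, y, seed = 3)
  expect_lt(tail(ft3$loss_history, 1), ft3$loss_history[1])
})

test_that("fusion concatenates columns, preserves origins and guards labels", {
  p <- feature_gen_params(n_per_class = 3,
                          dims_per_extractor = c(deit3_base_p16 = 20L,
                                                 swin_base_p4w7 = 30L,
                                                 vit_base_p16 = 20L),
                          informative_frac = 0.2, duplicate_frac = 0,
                          seed = 5)
  sets <- gen_feature_dataset(p)
  fused2 <- fuse(sets$deit3_base_p16, sets$vit_base_p16)
  expect_equal(ncol(feature_values(fused2)), 40)
  fused3 <- fuse(sets)
  expect_equal(ncol(feature_values(fused3)), 70)
  # single input: returned unchanged
  expect_identical(fuse(list(sets$deit3_base_p16)), sets$deit3_base_p16)
  # slicing by origin recovers the originals exactly
  back <- slice_by_origin(fused3, "swin_base_p4w7")
  expect_equal(feature_values(back), feature_values(sets$swin_base_p4w7))
  expect_identical(back$label, sets$swin_base_p4w7$label)
  # label mismatch is a hard error
  tampered <- sets$vit_base_p16
  tampered$label <- rev(tampered$label)
  expect_error(fuse(sets$deit3_base_p16, tampered), "label")
})

test_that("feature tables round-trip through CSV with origin sidecars", {
  p <- feature_gen_params(n_per_class = 2, dims_per_extractor = c(a = 6L),
                          informative_frac = 0.5, duplicate_frac = 0, seed = 6)
  fm <- gen_feature_dataset(p)$a
  path <- tempfile(fileext = ".csv")
  write_features_csv(fm, path)
  expect_equal(names(read.csv(path))[1], "f_0001")
  got <- read_features_csv(path)
  expect_equal(feature_values(got), feature_values(fm), tolerance = 1e-12)
  expect_identical(attr(got, "origin"), attr(fm, "origin"))
  unlink(c(path, paste0(path, ".origin.json")))
})

test_that("relevance ranking puts a label copy first and skips fresh duplicates", {
  set.seed(8)
  n <- 120
  y <- rep(0:3, each = 30)
  f1 <- y + rnorm(n, sd = 1)            # informative
  f2 <- f1                               # exact copy of f1
  f3 <- y + rnorm(n, sd = 3)             # weakly informative, independent
  ycopy <- as.numeric(y)                 # a column equal to the label
  fm <- gisegnet:::feature_matrix(cbind(f1, f2, f3, ycopy), y,
                                  origin = rep("t", 4))
  r <- mrmr_rank(fm, 4)
  expect_equal(r$ranked_idx[1], 4)       # the label copy is maximally relevant
  # among {f1 copy-pair, f3}: the copy is never taken right after its source
  fm2 <- gisegnet:::feature_matrix(cbind(f1, f2, f3), y, origin = rep("t", 3))
  r2 <- mrmr_rank(fm2, 3)
  expect_equal(r2$ranked_idx[1], 1)      # ties break to the lowest index
  expect_equal(r2$ranked_idx[2], 3)      # redundancy penalty defers the copy
})

test_that("greedy selection agrees with the brute-force oracle on small instances", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 60
    y <- sample(0:2, n, replace = TRUE)
    X <- cbind(y + rnorm(n), rnorm(n), y * 2 + rnorm(n, sd = 2),
               rnorm(n), y + rnorm(n, sd = 0.5))
    fm <- gisegnet:::feature_matrix(X, y, origin = rep("t", 5))
    r <- mrmr_rank(fm, 5)
    # oracle works on the same binned representation, independent greedy code
    B <- vapply(seq_len(5), function(j) gisegnet:::ef_bin(X[, j], 10L),
                integer(n))
    want <- oracle_mrmr(B, y, 5)
    expect_equal(r$ranked_idx, want)
  }
})

test_that("rankings are exhaustive permutations with the prefix property", {
  set.seed(10)
  n <- 50
  y <- sample(0:1, n, replace = TRUE)
  X <- matrix(rnorm(n * 8), n, 8)
  X[, 2] <- y + rnorm(n, sd = 0.5)
  fm <- gisegnet:::feature_matrix(X, y, origin = rep("t", 8))
  full <- mrmr_rank(fm, 8)
  expect_setequal(full$ranked_idx, 1:8)
  for (j in c(2, 5)) {
    expect_equal(mrmr_rank(fm, j)$ranked_idx, full$ranked_idx[1:j])
  }
  expect_error(mrmr_rank(fm, 9), "exceeds")
  # constant column: zero relevance, still selectable, deferred behind any
  # column with positive net score
  X2 <- cbind(y + rnorm(n, sd = 0.2), rep(1, n))
  fm2 <- gisegnet:::feature_matrix(X2, y, origin = rep("t", 2))
  expect_equal(mrmr_rank(fm2, 2)$ranked_idx, c(1, 2))
})

test_that("the cubic SVM separates what is separable", {
  set.seed(11)
  tr <- rbind(matrix(rnorm(40, mean = 0), 20), matrix(rnorm(40, mean = 4), 20))
  te <- rbind(matrix(rnorm(20, mean = 0), 10), matrix(rnorm(20, mean = 4), 10))
  fm_tr <- gisegnet:::feature_matrix(tr, rep(c(0L, 1L), each = 20),
                                     origin = rep("t", 2))
  fm_te <- gisegnet:::feature_matrix(te, rep(c(0L, 1L), each = 10),
                                     origin = rep("t", 2))
  pred <- svm_train_predict(fm_tr, fm_te)
  expect_equal(pred, rep(c(0L, 1L), each = 10))
  expect_true(all(pred %in% fm_tr$label))
  # train = test on a tiny separable 8-class set: accuracy 1
  set.seed(12)
  X8 <- do.call(rbind, lapply(0:7, function(k) {
    matrix(rnorm(10 * 3, mean = 6 * k), 10)
  }))
  fm8 <- gisegnet:::feature_matrix(X8, rep(0:7, each = 10),
                                   origin = rep("t", 3))
  expect_equal(mean(svm_train_predict(fm8, fm8) == fm8$label), 1)
  # single-class training set is rejected
  one <- gisegnet:::feature_matrix(matrix(rnorm(20), 10), rep(1L, 10),
                                   origin = rep("t", 2))
  expect_error(svm_train_predict(one, one), "two classes")
})

test_that("stratified folds balance every class and validate sizes", {
  y <- rep(0:3, times = c(10, 10, 11, 12))
  fid <- gisegnet:::stratified_folds(y, 5, seed = 1)
  for (cls in 0:3) {
    sizes <- table(fid[y == cls])
    expect_lte(diff(range(sizes)), 1)
  }
  expect_error(gisegnet:::stratified_folds(rep(0:1, c(3, 10)), 5, 1),
               "at least")
})

test_that("cross-validation is perfect on separable data and tidies cleanly", {
  set.seed(13)
  X <- do.call(rbind, lapply(0:3, function(k) matrix(rnorm(15 * 2, mean = 8 * k), 15)))
  fm <- gisegnet:::feature_matrix(X, rep(0:3, each = 15), origin = rep("t", 2))
  cv <- crossval_accuracy(fm, folds = 5, seed = 2)
  expect_equal(cv$accuracy, 1)
  expect_equal(sum(cv$confusion), 60)
  expect_equal(unname(diag(cv$confusion)), c(15, 15, 15, 15))
  expect_equal(nrow(tidy(cv)), 5)
  expect_equal(glance(cv)$accuracy, 1)
  # determinism under the seed
  expect_equal(crossval_accuracy(fm, folds = 5, seed = 2)$accuracy, cv$accuracy)
})
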