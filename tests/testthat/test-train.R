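test_that("dataset splitting sizes, determinism and degenerate cases", {
  sp <- split_dataset(1:1000, c(0.8, 0.1, 0.1), seed = 3)
  expect_equal(lengths(sp), c(train = 800, test = 100, val = 100))
  expect_setequal(c(sp$train, sp$test, sp$val), 1:1000)
  expect_equal(length(intersect(sp$train, sp$test)), 0)

  sp_all <- split_dataset(1:10, c(1, 0, 0), seed = 1)
  expect_equal(length(sp_all$train), 10)
  expect_equal(length(sp_all$test), 0)

  expect_identical(split_dataset(1:50, seed = 9), split_dataset(1:50, seed = 9))
  expect_false(identical(split_dataset(1:50, seed = 9)$train,
                         split_dataset(1:50, seed = 10)$train))
  expect_error(split_dataset(integer(0)), "non-empty")
  expect_error(split_dataset(1:10, c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("protocol validation enforces its invariants", {
  expect_error(train_protocol(lr_init = 1e-6, lr_min = 1e-5), "lr_min")
  expect_error(train_protocol(batch = 0), "batch")
  expect_error(train_protocol(split = c(0.7, 0.2, 0.2)), "sum to 1")
  p <- train_protocol()
  expect_equal(p$lr_init, 0.01)
  expect_equal(p$lr_min, 1e-5)
  expect_equal(p$batch, 16L)
  expect_equal(p$epochs, 100L)
  expect_equal(p$split, c(0.8, 0.1, 0.1))
})

test_that("zero epochs leave the model untouched with an empty history", {
  set.seed(1)
  model <- build_gisegnet(gisegnet_config(input_size = c(16L, 16L, 3L),
                                          depth = 1L, widths = 4L))
  w_before <- model$params[[1]]$value
  data <- gen_seg_arrays(seg_scene_params(n_images = 2, size = 32, seed = 1))
  data$images <- data$images[1:16, 1:16, , , drop = FALSE]
  data$masks <- data$masks[1:16, 1:16, , , drop = FALSE]
  out <- train_segmentation(model, data,
                            train_protocol(epochs = 0, input = c(16, 16)))
  expect_equal(nrow(out$history), 0)
  expect_identical(model$params[[1]]$value, w_before)
})

test_that("a short run learns, logs a complete history and keeps the LR schedule", {
  set.seed(2)
  model <- build_gisegnet(gisegnet_config(input_size = c(32L, 32L, 3L),
                                          depth = 2L, widths = c(4L, 8L)))
  data <- gen_seg_arrays(seg_scene_params(n_images = 24, size = 32, seed = 11))
  proto <- train_protocol(epochs = 4, batch = 8, input = c(32, 32),
                          patience = 1, seed = 5)
  model <- train_segmentation(model, data, proto)
  h <- model$history
  expect_equal(nrow(h), 4)
  expect_true(all(is.finite(h$loss)))
  expect_lt(h$loss[4], h$loss[1])  # the blob task is learnable
  # learning rate never increases and never undercuts the floor
  expect_true(all(diff(h$lr) <= 0))
  expect_true(all(h$lr >= proto$lr_min))
  # reproducible: same seeds, same model init, same losses
  set.seed(2)
  model2 <- build_gisegnet(gisegnet_config(input_size = c(32L, 32L, 3L),
                                           depth = 2L, widths = c(4L, 8L)))
  model2 <- train_segmentation(model2, data, proto)
  expect_equal(model2$history$loss, h$loss, tolerance = 1e-12)
})

test_that("validation data drives the plateau monitor and val metrics", {
  set.seed(3)
  model <- build_gisegnet(gisegnet_config(input_size = c(16L, 16L, 3L),
                                          depth = 1L, widths = 4L))
  mk <- function(seed) {
    d <- gen_seg_arrays(seg_scene_params(n_images = 8, size = 32, seed = seed))
    list(images = d$images[1:16, 1:16, , , drop = FALSE],
         masks = d$masks[1:16, 1:16, , , drop = FALSE])
  }
  model <- train_segmentation(model, mk(1),
                              train_protocol(epochs = 2, batch = 4,
                                             input = c(16, 16)),
                              val = mk(2))
  expect_true(all(is.finite(model$history$val_loss)))
  expect_true(all(is.finite(model$history$val_dice)))
})

test_that("disk datasets round-trip through the loader", {
  dir <- tempfile("segset")
  params <- seg_scene_params(n_images = 3, size = 32, seed = 4)
  files <- gen_seg_dataset(params, dir)
  ds <- load_seg_dataset(dir)
  expect_equal(dim(ds$images), c(32, 32, 3, 3))
  expect_equal(dim(ds$masks), c(32, 32, 1, 3))
  expect_true(all(ds$masks %in% c(0, 1)))
  # resizing keeps masks binary
  ds2 <- load_seg_dataset(dir, size = c(16, 16))
  expect_equal(dim(ds2$images), c(16, 16, 3, 3))
  expect_true(all(ds2$masks %in% c(0, 1)))
  unlink(dir, recursive = TRUE)
})

test_that("history files are written in both formats", {
  h <- tibble::tibble(epoch = 1:2, loss = c(0.5, 0.4), val_loss = c(NA, NA),
                      dice = c(0.6, 0.7), val_dice = c(NA, NA),
                      jaccard = c(0.4, 0.5), val_jaccard = c(NA, NA),
                      acc = c(0.8, 0.9), val_acc = c(NA, NA), lr = c(0.01, 0.01))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_history(h, csv, js)
  expect_equal(nrow(read.csv(csv)), 2)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$loss, c(0.5, 0.4))
})
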