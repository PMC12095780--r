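test_that("scene generation is deterministic down to the written bytes", {
  d1 <- tempfile("gen1"); d2 <- tempfile("gen2")
  p <- seg_scene_params(n_images = 3, size = 64, seed = 3)
  gen_seg_dataset(p, d1)
  gen_seg_dataset(p, d2)
  for (sub in c("images", "masks")) {
    f1 <- sort(list.files(file.path(d1, sub), full.names = TRUE))
    f2 <- sort(list.files(file.path(d2, sub), full.names = TRUE))
    expect_equal(length(f1), 3)
    for (k in seq_along(f1)) {
      expect_identical(readBin(f1[k], "raw", file.size(f1[k])),
                       readBin(f2[k], "raw", file.size(f2[k])))
    }
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("every generated mask is binary and non-empty with lesions present", {
  p <- seg_scene_params(n_images = 6, size = 48, seed = 5)
  d <- gen_seg_arrays(p)
  expect_true(all(d$masks %in% c(0, 1)))
  for (i in 1:6) expect_gt(sum(d$masks[, , 1, i]), 0)
  expect_true(all(d$images >= 0 & d$images <= 1))
  expect_true(all(is.finite(d$images)))
})

test_that("a single rasterized ellipse covers roughly pi*a*b pixels", {
  a <- 10; b <- 14
  p <- seg_scene_params(n_images = 8, size = 96,
                        lesion_count_range = c(1L, 1L),
                        lesion_axis_range = c(a, b), seed = 6)
  # oracle: direct pixel count of the analytic ellipse equation at the
  # drawn axes; with axes free in [a, b] the area must lie within the
  # discretization band around pi * ax * bx -- check via the generator's
  # degenerate range instead (ax = bx fixed)
  pfix <- seg_scene_params(n_images = 8, size = 96,
                           lesion_count_range = c(1L, 1L),
                           lesion_axis_range = c(12, 12), seed = 6)
  d <- gen_seg_arrays(pfix)
  for (i in 1:8) {
    area <- sum(d$masks[, , 1, i])
    expect_lt(abs(area - pi * 12 * 12) / (pi * 12 * 12), 0.05)
  }
  expect_error(seg_scene_params(size = 32, lesion_axis_range = c(20, 20)),
               "fit inside")
  expect_error(seg_scene_params(size = 16), ">= 32")
})

test_that("sub-seeding makes images independent of generation order", {
  p <- seg_scene_params(n_images = 5, size = 48, seed = 9)
  direct <- gen_seg_scene(p, 4)
  all <- gen_seg_arrays(p)
  expect_equal(all$images[, , , 4], direct$image)
  expect_equal(all$masks[, , 1, 4], direct$mask + 0)
})

test_that("feature generation plants informative, duplicate and noise columns", {
  p <- feature_gen_params(n_per_class = 5,
                          dims_per_extractor = c(a = 100L, b = 60L),
                          informative_frac = 0.1, duplicate_frac = 0.1,
                          class_sep = 2, seed = 2)
  sets <- gen_feature_dataset(p)
  expect_named(sets, c("a", "b"))
  fa <- sets$a
  expect_equal(dim(feature_values(fa)), c(40, 100))
  roles <- attr(fa, "roles")
  expect_equal(sum(roles == "informative"), 10)
  expect_equal(sum(roles == "duplicate"), 10)
  # duplicates correlate exactly with their recorded source
  X <- feature_values(fa)
  dup_of <- attr(fa, "duplicate_of")
  for (j in which(roles == "duplicate")) {
    expect_identical(X[, j], X[, dup_of[j]])
  }
  # labels and order are shared across extractors
  expect_identical(sets$a$label, sets$b$label)
  expect_true(all(is.finite(X)))
  # determinism
  sets2 <- gen_feature_dataset(p)
  expect_identical(sets, sets2)
})

test_that("parameter validation rejects impossible fraction requests", {
  expect_error(feature_gen_params(dims_per_extractor = c(a = 10L),
                                  informative_frac = 0.6, duplicate_frac = 0.6),
               "too few dimensions")
  expect_error(feature_gen_params(dims_per_extractor = c(a = 100L),
                                  informative_frac = 0.05, duplicate_frac = 0.2),
               "informative sources")
})

test_that("class separation controls the learnable signal", {
  p0 <- feature_gen_params(n_per_class = 10,
                           dims_per_extractor = c(a = 40L),
                           informative_frac = 0.25, duplicate_frac = 0,
                           class_sep = 0, seed = 3)
  X0 <- feature_values(gen_feature_dataset(p0)$a)
  p5 <- feature_gen_params(n_per_class = 10,
                           dims_per_extractor = c(a = 40L),
                           informative_frac = 0.25, duplicate_frac = 0,
                           class_sep = 5, seed = 3)
  s5 <- gen_feature_dataset(p5)$a
  X5 <- feature_values(s5)
  # between-class spread of informative columns grows with class_sep
  spread <- function(X, y) {
    mean(vapply(1:10, function(j) {
      var(tapply(X[, j], y, mean))
    }, numeric(1)))
  }
  expect_gt(spread(X5, s5$label), 10 * spread(X0, s5$label))
})
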