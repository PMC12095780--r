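test_that("effective receptive field follows the dilated-kernel formula", {
  cases <- list(
    list(n = 3, a_x = 1, a_y = 1, exp = c(3, 3, 9)),
    list(n = 3, a_x = 2, a_y = 2, exp = c(5, 5, 25)),
    list(n = 3, a_x = 6, a_y = 12, exp = c(13, 25, 325))
  )
  for (cs in cases) {
    rf <- effective_receptive_field(kernel_spec(cs$n, a_x = cs$a_x, a_y = cs$a_y))
    expect_equal(unlist(rf), c(height = cs$exp[1], width = cs$exp[2],
                               area = cs$exp[3]),
                 ignore_attr = TRUE)
  }
  # symmetric dilation reduces to the square formula [1 + (n-1)a]^2
  for (a in c(1, 2, 6, 18)) {
    rf <- effective_receptive_field(kernel_spec(3, a_x = a, a_y = a))
    expect_equal(rf$area, (1 + 2 * a)^2)
  }
})

test_that("kernel_spec validation names the violated invariant", {
  expect_error(kernel_spec(4), "odd")
  expect_error(kernel_spec(3, a_x = 0), "a_x")
  expect_error(kernel_spec(3, in_ch = 0), "in_ch")
  expect_error(kernel_spec(3, in_ch = 2, out_ch = 3, depthwise = TRUE),
               "depthwise")
})

test_that("decomposed weight counts follow the 2n-versus-n^2 rule", {
  s3 <- kernel_spec(3)
  expect_identical(conv_param_count(s3, decomposed = TRUE), 6L)
  expect_identical(conv_param_count(s3, decomposed = FALSE), 9L)
  # degenerate n = 1: decomposition is counter-productive but literal
  s1 <- kernel_spec(1)
  expect_identical(conv_param_count(s1, decomposed = TRUE), 2L)
  expect_identical(conv_param_count(s1, decomposed = FALSE), 1L)
  # n = 5 saves 60%
  s5 <- kernel_spec(5)
  expect_identical(conv_param_count(s5, decomposed = TRUE), 10L)
  expect_identical(conv_param_count(s5, decomposed = FALSE), 25L)
  expect_equal(1 - 10 / 25, 0.6)
  # channel fan multiplies the per-pair counts; depthwise uses in_ch only
  sf <- kernel_spec(3, in_ch = 4, out_ch = 8)
  expect_identical(conv_param_count(sf, TRUE), 6L * 32L)
  sdw <- kernel_spec(3, in_ch = 4, depthwise = TRUE)
  expect_identical(conv_param_count(sdw, TRUE), 6L * 4L)
  # decomposition always wins for odd n >= 3
  for (n in c(3L, 5L, 7L, 9L)) {
    sp <- kernel_spec(n)
    expect_lt(conv_param_count(sp, TRUE), conv_param_count(sp, FALSE))
  }
})

test_that("asymmetric convolution equals dense convolution with the rank-1 kernel", {
  set.seed(101)
  for (rep in 1:50) {
    layer <- asym_conv(kernel_spec(3, in_ch = 1, out_ch = 1, bias = FALSE))
    x <- array(rnorm(64), c(8, 8, 1))
    got <- layer_forward(layer, x)
    # rank-1 kernel k = k_v %o% k_h applied by the dense loop oracle
    kv <- layer$params$w_v$value[, 1, 1, 1]
    kh <- layer$params$w_h$value[1, , 1, 1]
    k2 <- array(kv %o% kh, c(3, 3, 1, 1))
    want <- oracle_conv2d(array(x, c(8, 8, 1, 1)), k2)
    expect_lt(max(abs(as.vector(got) - as.vector(want))), 1e-5)
  }
})

test_that("asymmetric layers honour zero-init, shape and trainable-count contracts", {
  set.seed(5)
  layer <- asym_conv(kernel_spec(3, in_ch = 2, out_ch = 4))
  set_all_params(layer, 0)
  x <- array(rnorm(7 * 9 * 2), c(7, 9, 2))
  expect_true(all(layer_forward(layer, x) == 0))
  # shape contract H x W x out_ch for H, W >= n
  set.seed(6)
  layer2 <- asym_conv(kernel_spec(3, in_ch = 2, out_ch = 4))
  expect_equal(dim(layer_forward(layer2, x)), c(7, 9, 4))
  # trainable count = decomposed weights plus biases at equal fan (the
  # network always uses the pair at C -> C)
  spec4 <- kernel_spec(3, in_ch = 4, out_ch = 4)
  set.seed(7)
  layer4 <- asym_conv(spec4)
  expect_identical(count_parameters(layer4),
                   conv_param_count(spec4, TRUE) + 2L * 4L)
  nb <- asym_conv(kernel_spec(3, in_ch = 1, out_ch = 1, bias = FALSE))
  expect_identical(count_parameters(nb), 6L)
})

test_that("all builders preserve spatial size for every study dilation rate", {
  set.seed(11)
  x <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  for (a in c(1L, 6L, 12L, 18L)) {
    dense <- asym_conv(kernel_spec(3, in_ch = 3, out_ch = 2, a_x = a, a_y = a))
    expect_equal(dim(layer_forward(dense, x))[1:2], c(12, 12))
    dw <- depthwise_asym_conv(kernel_spec(3, in_ch = 3, depthwise = TRUE,
                                          a_x = a, a_y = a))
    expect_equal(dim(layer_forward(dw, x)), c(12, 12, 3))
  }
})

test_that("depthwise pairs keep channels independent and match loop oracles", {
  set.seed(21)
  layer <- depthwise_asym_conv(kernel_spec(3, in_ch = 3, depthwise = TRUE,
                                           bias = FALSE))
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  x[, , 1] <- 0
  out <- layer_forward(layer, x)
  expect_true(all(out[, , 1] == 0))  # zero channel in, zero channel out
  # per-channel brute force: each channel sees only its own 1-D kernel pair
  for (c in 1:3) {
    wv <- array(layer$params$w_v$value[, , c], c(3, 1, 1, 1))
    wh <- array(layer$params$w_h$value[, , c], c(1, 3, 1, 1))
    want <- oracle_asym_pair(array(x[, , c], c(6, 6, 1, 1)), wv, NULL, wh, NULL)
    expect_lt(max(abs(out[, , c] - want[, , 1, 1])), 1e-10)
  }
})

test_that("depthwise at one channel coincides with the dense pair", {
  set.seed(31)
  dw <- depthwise_asym_conv(kernel_spec(3, in_ch = 1, depthwise = TRUE))
  dense <- asym_conv(kernel_spec(3, in_ch = 1, out_ch = 1))
  # copy the depthwise weights into the dense layer
  dense$params$w_v$value <- array(dw$params$w_v$value, c(3, 1, 1, 1))
  dense$params$w_h$value <- array(dw$params$w_h$value, c(1, 3, 1, 1))
  dense$params$b_v$value <- dw$params$b_v$value
  dense$params$b_h$value <- dw$params$b_h$value
  x <- array(rnorm(25), c(5, 5, 1))
  expect_equal(layer_forward(dw, x), layer_forward(dense, x), tolerance = 1e-12)
})
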