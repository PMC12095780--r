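# Encoder-Decoder-Residual (EDR) block: a 1x1 projection with batch
# normalization and ReLU, followed by two rounds of parallel asymmetric
# (dense) and depthwise-asymmetric branches merged by elementwise addition,
# closed by a residual shortcut from the projection output.

# 3x1 / 1x3 dense pair with BN + ReLU after each 1-D convolution.
acb_block <- function(width) {
  children <- list(
    cv = conv_layer(3L, 1L, width, width),
    ch = conv_layer(1L, 3L, width, width)
  )
  params <- list(
    g1 = ag_param(rep(1, width)), be1 = ag_param(numeric(width)),
    g2 = ag_param(rep(1, width)), be2 = ag_param(numeric(width))
  )
  states <- list(bn1 = new_bn_state(width), bn2 = new_bn_state(width))
  layer <- new_layer(function(x, training = FALSE) {
    h <- children$cv$forward(x, training = training)
    h <- ag_relu(ag_bn(h, params$g1, params$be1, states$bn1, training = training))
    h <- children$ch$forward(h, training = training)
    ag_relu(ag_bn(h, params$g2, params$be2, states$bn2, training = training))
  }, params = params, children = children, class = "acb_block")
  layer$states <- states
  layer
}

# Depthwise 3x1 / 1x3 pair, BN + ReLU after each half; channels never mix.
adb_block <- function(width) {
  children <- list(
    dw = depthwise_asym_conv(kernel_spec(3L, in_ch = width, depthwise = TRUE))
  )
  params <- list(
    g1 = ag_param(rep(1, width)), be1 = ag_param(numeric(width)),
    g2 = ag_param(rep(1, width)), be2 = ag_param(numeric(width))
  )
  states <- list(bn1 = new_bn_state(width), bn2 = new_bn_state(width))
  dwp <- children$dw$params
  layer <- new_layer(function(x, training = FALSE) {
    h <- ag_dwconv2d(x, dwp$w_v, dwp$b_v, dil_h = 1L, dil_w = 1L)
    h <- ag_relu(ag_bn(h, params$g1, params$be1, states$bn1, training = training))
    h <- ag_dwconv2d(h, dwp$w_h, dwp$b_h, dil_h = 1L, dil_w = 1L)
    ag_relu(ag_bn(h, params$g2, params$be2, states$bn2, training = training))
  }, params = params, children = children, class = "adb_block")
  layer$states <- states
  layer
}

#' Build an Encoder-Decoder-Residual (EDR) block
#'
#' The incoming map is projected to `width` channels by a 1x1 convolution
#' with batch normalization and ReLU. Two successive enhancement stages then
#' each apply a dense asymmetric branch (ACB: 3x1 then 1x3 convolutions) and
#' a depthwise asymmetric branch (ADB) in parallel and merge them by
#' elementwise addition; the block output adds the projection back as a
#' residual shortcut. Spatial size is preserved; output channels equal
#' `width`.
#'
#' @param in_ch Incoming channel count.
#' @param width Channel width of the block (and of its output).
#' @return A layer; apply with [layer_forward()].
#' @examples
#' set.seed(1)
#' blk <- build_edr(3, 8)
#' out <- layer_forward(blk, array(runif(16 * 16 * 3), c(16, 16, 3)))
#' dim(out)  # 16 16 8
#' @export
build_edr <- function(in_ch, width) {
  children <- list(
    proj = conv_layer(1L, 1L, in_ch, width),
    acb1 = acb_block(width), adb1 = adb_block(width),
    acb2 = acb_block(width), adb2 = adb_block(width)
  )
  params <- list(g0 = ag_param(rep(1, width)), be0 = ag_param(numeric(width)))
  states <- list(bn0 = new_bn_state(width))
  layer <- new_layer(function(x, training = FALSE) {
    if (any(!is.finite(x$value))) abort("edr block received non-finite input")
    f1 <- ag_relu(ag_bn(children$proj$forward(x, training = training),
                        params$g0, params$be0, states$bn0, training = training))
    a <- ag_add(children$acb1$forward(f1, training = training),
                children$adb1$forward(f1, training = training))
    b <- ag_add(children$acb2$forward(a, training = training),
                children$adb2$forward(a, training = training))
    ag_add(f1, b)
  }, params = params, children = children, class = "edr_block")
  layer$states <- states
  layer
}
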