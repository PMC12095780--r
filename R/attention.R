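# Hybrid attention: a spatial gate built from multi-rate atrous branches
# (ESAM), a squeeze-excitation style channel gate driven by global average
# pooling (ECAM), and their composition (EHAAC) which re-convolves the gated
# sum with a dilated fusion convolution.

#' Build the multi-rate spatial attention gate (ESAM)
#'
#' One branch per dilation rate: a 3x3 atrous convolution realized as an
#' asymmetric pair (3x1 then 1x3, both dilated at the branch rate), keeping
#' the channel count. The gate returns
#' `sum_i sigmoid(d_i(F)) * d_i(F)` over the branch outputs `d_i`,
#' elementwise, so strongly responding locations are emphasized at several
#' receptive-field scales at once. Branches have independent weights.
#'
#' @param channels Channel count `C` of the incoming feature map.
#' @param rates Integer dilation rates, one branch each. Default
#'   `c(1, 6, 12, 18)`.
#' @return A layer; apply with [layer_forward()].
#' @export
build_esam <- function(channels, rates = c(1L, 6L, 12L, 18L)) {
  if (length(rates) < 1L) abort("esam needs a non-empty dilation rate set")
  branches <- lapply(rates, function(r) {
    asym_conv(kernel_spec(3L, in_ch = channels, out_ch = channels,
                          a_x = as.integer(r), a_y = as.integer(r)))
  })
  names(branches) <- paste0("rate", rates)
  new_layer(function(x, training = FALSE) {
    out <- NULL
    for (br in branches) {
      d <- br$forward(x, training = training)
      term <- ag_mul(ag_sigmoid(d), d)
      out <- if (is.null(out)) term else ag_add(out, term)
    }
    out
  }, children = branches, class = "esam")
}

#' Build the channel attention gate (ECAM)
#'
#' Per-channel spatial means (global average pooling) pass through a
#' squeeze-excitation pair of linear maps with sigmoid activations
#' (`C -> C/r -> C`), then a pointwise `C -> C` map; the resulting channel
#' weight vector multiplies the feature map, broadcast over space. As
#' written, the gate has no outer squashing and may exceed 1; set
#' `bounded = TRUE` to append a sigmoid.
#'
#' @param channels Channel count `C`.
#' @param reduction Reduction ratio `r` of the bottleneck width
#'   (`max(1, C %/% r)` units). Default 4.
#' @param bounded Append a sigmoid to the channel weights.
#' @return A layer; apply with [layer_forward()].
#' @export
build_ecam <- function(channels, reduction = 4L, bounded = FALSE) {
  if (reduction < 1L) abort("ecam reduction ratio must be >= 1")
  cr <- max(1L, channels %/% as.integer(reduction))
  sdev <- function(fan) sqrt(2 / fan)
  params <- list(
    w1 = ag_param(matrix(rnorm(cr * channels, sd = sdev(channels)), cr, channels)),
    b1 = ag_param(numeric(cr)),
    w2 = ag_param(matrix(rnorm(channels * cr, sd = sdev(cr)), channels, cr)),
    b2 = ag_param(numeric(channels)),
    v = ag_param(matrix(rnorm(channels * channels, sd = sdev(channels)), channels, channels)),
    bv = ag_param(numeric(channels))
  )
  new_layer(function(x, training = FALSE) {
    C <- dim(x$value)[3]
    if (C != channels) {
      abort(sprintf("ecam built for %d channels, got a %d-channel map", channels, C))
    }
    g <- ag_gap(x)
    g <- ag_sigmoid(ag_dense(params$w1, g, params$b1))
    g <- ag_sigmoid(ag_dense(params$w2, g, params$b2))
    g <- ag_dense(params$v, g, params$bv)
    if (bounded) g <- ag_sigmoid(g)
    ag_scale_channels(x, g)
  }, params = params, class = "ecam")
}

#' Build the hybrid attentional atrous convolution module (EHAAC)
#'
#' Composition of the two gates: the spatial gate runs first
#' (`F_esam = ESAM(F)`), the channel gate is computed on the spatially gated
#' map, the two are summed, and a final 3x3 dilated asymmetric convolution at
#' `out_rate` fuses the result:
#' `EHAAC(F) = d_out( ECAM(ESAM(F)) + ESAM(F) )`.
#' Shape is preserved throughout.
#'
#' @inheritParams build_esam
#' @param reduction ECAM reduction ratio.
#' @param out_rate Dilation rate of the fusion convolution (default 1).
#' @param bounded Bound the ECAM channel weights with a sigmoid.
#' @return A layer; apply with [layer_forward()].
#' @export
build_ehaac <- function(channels, rates = c(1L, 6L, 12L, 18L), reduction = 4L,
                        out_rate = 1L, bounded = FALSE) {
  children <- list(
    esam = build_esam(channels, rates),
    ecam = build_ecam(channels, reduction, bounded = bounded),
    fuse = asym_conv(kernel_spec(3L, in_ch = channels, out_ch = channels,
                                 a_x = as.integer(out_rate),
                                 a_y = as.integer(out_rate)))
  )
  new_layer(function(x, training = FALSE) {
    fe <- children$esam$forward(x, training = training)
    fc <- children$ecam$forward(fe, training = training)
    children$fuse$forward(ag_add(fc, fe), training = training)
  }, children = children, class = "ehaac")
}
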