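# Convolution building blocks: standard, asymmetric (n x 1 then 1 x n),
# atrous-asymmetric and depthwise-asymmetric, plus analytic calculators for
# receptive fields and parameter counts. The asymmetric decomposition factors
# an n x n kernel into two sequential one-dimensional kernels, costing 2n
# weights per channel pair instead of n^2.

#' Describe one convolution primitive
#'
#' A kernel specification captures everything needed to build or reason about
#' one convolution: the (odd) kernel size `n`, channel fan-in/out, per-axis
#' dilation rates, and whether the convolution is depthwise (per-channel,
#' no channel mixing).
#'
#' @param n Odd kernel size in pixels.
#' @param in_ch,out_ch Input and output channel counts.
#' @param a_x,a_y Integer dilation rates along the vertical (x) and horizontal
#'   (y) axes; 1 means a standard dense kernel.
#' @param depthwise If `TRUE` the kernel acts independently per channel and
#'   `out_ch` must equal `in_ch`.
#' @param bias Whether the built layers carry bias terms. Biases are never
#'   included in [conv_param_count()], which follows the weight-only
#'   2n-versus-n^2 accounting.
#'
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec(3, a_x = 6, a_y = 12)
#' @export
kernel_spec <- function(n = 3L, in_ch = 1L, out_ch = in_ch, a_x = 1L, a_y = 1L,
                        depthwise = FALSE, bias = TRUE) {
  n <- as.integer(n); in_ch <- as.integer(in_ch); out_ch <- as.integer(out_ch)
  a_x <- as.integer(a_x); a_y <- as.integer(a_y)
  if (n < 1L || n %% 2L == 0L) {
    abort(sprintf("invalid kernel_spec: `n` must be odd and >= 1 (got %d)", n))
  }
  if (a_x < 1L) abort(sprintf("invalid kernel_spec: `a_x` must be >= 1 (got %d)", a_x))
  if (a_y < 1L) abort(sprintf("invalid kernel_spec: `a_y` must be >= 1 (got %d)", a_y))
  if (in_ch < 1L) abort(sprintf("invalid kernel_spec: `in_ch` must be >= 1 (got %d)", in_ch))
  if (out_ch < 1L) abort(sprintf("invalid kernel_spec: `out_ch` must be >= 1 (got %d)", out_ch))
  if (depthwise && out_ch != in_ch) {
    abort("invalid kernel_spec: depthwise requires `out_ch` == `in_ch`")
  }
  structure(
    list(n = n, in_ch = in_ch, out_ch = out_ch, a_x = a_x, a_y = a_y,
         depthwise = isTRUE(depthwise), bias = isTRUE(bias)),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf(
    "<kernel_spec> n=%d %s %d->%d channels, dilation (%d, %d)%s\n",
    x$n, if (x$depthwise) "depthwise" else "dense", x$in_ch, x$out_ch,
    x$a_x, x$a_y, if (x$bias) ", bias" else ""
  ))
  invisible(x)
}

#' Effective receptive field of a (possibly dilated) asymmetric kernel pair
#'
#' Two sequential one-dimensional dilated kernels of size `n` span
#' `1 + (n - 1) a_x` pixels vertically and `1 + (n - 1) a_y` pixels
#' horizontally; the total spatial receptive field is their product.
#'
#' @param spec A [kernel_spec()].
#' @return A one-row tibble with columns `height`, `width` and `area`
#'   (pixels and pixels squared).
#' @examples
#' effective_receptive_field(kernel_spec(3, a_x = 6, a_y = 12))
#' @export
effective_receptive_field <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  h <- 1L + (spec$n - 1L) * spec$a_x
  w <- 1L + (spec$n - 1L) * spec$a_y
  tibble(height = h, width = w, area = h * w)
}

#' Weight count of a convolution, standard versus decomposed
#'
#' Counts trainable kernel weights (biases excluded). Per input-output channel
#' pair a standard `n x n` kernel holds `n^2` weights; the asymmetric
#' decomposition into an `n x 1` plus a `1 x n` kernel holds `2n`. The full
#' count multiplies by the channel fan: `in_ch * out_ch` for dense kernels,
#' `in_ch` for depthwise. At `n = 3` the decomposition saves 33% of the
#' weights (6 versus 9); at `n = 1` it is counter-productive (2 versus 1) and
#' the literal count is still returned.
#'
#' @param spec A [kernel_spec()].
#' @param decomposed Count the asymmetric pair (`TRUE`) or the dense
#'   `n x n` kernel (`FALSE`).
#' @return Integer weight count.
#' @examples
#' conv_param_count(kernel_spec(3), decomposed = TRUE)   # 6
#' conv_param_count(kernel_spec(3), decomposed = FALSE)  # 9
#' @export
conv_param_count <- function(spec, decomposed = FALSE) {
  stopifnot(inherits(spec, "kernel_spec"))
  fan <- if (spec$depthwise) spec$in_ch else spec$in_ch * spec$out_ch
  per_pair <- if (decomposed) 2L * spec$n else spec$n^2
  as.integer(per_pair * fan)
}

# ---- layer protocol ---------------------------------------------------------

# A layer is a list with `params` (named ag_param nodes), optional `children`
# (sub-layers) and `forward(x_node, training)`.
new_layer <- function(forward, params = list(), children = list(),
                      class = character()) {
  structure(list(forward = forward, params = params, children = children),
            class = c(class, "gi_layer"))
}

# All trainable parameter nodes of a layer, recursively.
layer_params <- function(layer) {
  c(layer$params, unlist(lapply(layer$children, layer_params), use.names = FALSE))
}

#' Number of trainable scalars in a layer or model
#'
#' Sums the lengths of every trainable weight and bias array.
#'
#' @param x A layer built by [asym_conv()] and friends, or a model from
#'   [build_gisegnet()].
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "gisegnet_model")) x <- x$net
  stopifnot(inherits(x, "gi_layer"))
  as.integer(sum(vapply(layer_params(x), function(p) length(p$value), numeric(1))))
}

#' Apply a layer to a feature map
#'
#' Runs a layer's forward pass on a plain numeric array. Arrays may be
#' `H x W x C` (one sample) or `H x W x C x N` (a batch); the output matches.
#'
#' @param layer A layer object.
#' @param x Numeric array.
#' @param training Use batch statistics in any normalization layers.
#' @return Numeric array of the layer's output.
#' @export
layer_forward <- function(layer, x, training = FALSE) {
  stopifnot(inherits(layer, "gi_layer"))
  x <- as_batch(x)
  out <- layer$forward(ag_const(x$arr), training = training)$value
  if (x$had_batch) out else array(out, dim = dim(out)[1:3])
}

as_batch <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    list(arr = x, had_batch = FALSE)
  } else if (length(d) == 4L) {
    list(arr = x, had_batch = TRUE)
  } else {
    abort("feature maps must be H x W x C or H x W x C x N arrays")
  }
}

# He-normal initialization for a conv kernel of dim (kh, kw, cin, cout).
init_conv_w <- function(kh, kw, cin, cout = NULL) {
  d <- c(kh, kw, cin, cout)
  fan_in <- kh * kw * cin
  array(rnorm(prod(d), sd = sqrt(2 / fan_in)), dim = d)
}

#' Build an asymmetric (n x 1 then 1 x n) convolution layer
#'
#' Applies a vertical `n x 1` convolution with dilation `a_x`, then a
#' horizontal `1 x n` convolution with dilation `a_y`, both with "same" zero
#' padding so spatial dimensions are preserved. With dilation 1 the pair is
#' algebraically a dense 2-D convolution with the rank-1 kernel `k_h %o% k_v`.
#' At equal channel fan (`in_ch == out_ch`, how every block in the network
#' uses the pair) its weight count equals
#' `conv_param_count(spec, decomposed = TRUE)`, i.e. `2n` per channel pair;
#' biases add `2 * out_ch`. Weights are drawn from a He-normal at build time
#' (seed via [set.seed()]).
#'
#' @param spec A dense [kernel_spec()] (`depthwise = FALSE`).
#' @return A layer; apply with [layer_forward()].
#' @examples
#' set.seed(1)
#' layer <- asym_conv(kernel_spec(3, in_ch = 1, out_ch = 1))
#' out <- layer_forward(layer, array(runif(25), c(5, 5, 1)))
#' @export
asym_conv <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$depthwise) abort("asym_conv requires a dense spec; see depthwise_asym_conv()")
  n <- spec$n
  params <- list(
    w_v = ag_param(init_conv_w(n, 1L, spec$in_ch, spec$out_ch)),
    w_h = ag_param(init_conv_w(1L, n, spec$out_ch, spec$out_ch))
  )
  if (spec$bias) {
    params$b_v <- ag_param(numeric(spec$out_ch))
    params$b_h <- ag_param(numeric(spec$out_ch))
  }
  a_x <- spec$a_x; a_y <- spec$a_y; bias <- spec$bias
  new_layer(function(x, training = FALSE) {
    h <- ag_conv2d(x, params$w_v, if (bias) params$b_v, dil_h = a_x, dil_w = 1L)
    ag_conv2d(h, params$w_h, if (bias) params$b_h, dil_h = 1L, dil_w = a_y)
  }, params = params, class = "asym_conv")
}

#' Build a depthwise asymmetric convolution layer
#'
#' Applies the `n x 1` then `1 x n` kernel pair independently per channel;
#' channels never mix. Per channel the pair holds `2n` weights (plus two
#' biases when enabled).
#'
#' @param spec A [kernel_spec()] with `depthwise = TRUE`.
#' @return A layer; apply with [layer_forward()].
#' @export
depthwise_asym_conv <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!spec$depthwise) abort("depthwise_asym_conv requires `depthwise = TRUE` (out_ch must equal in_ch)")
  n <- spec$n; C <- spec$in_ch
  params <- list(
    w_v = ag_param(array(rnorm(n * C, sd = sqrt(2 / n)), dim = c(n, 1L, C))),
    w_h = ag_param(array(rnorm(n * C, sd = sqrt(2 / n)), dim = c(1L, n, C)))
  )
  if (spec$bias) {
    params$b_v <- ag_param(numeric(C))
    params$b_h <- ag_param(numeric(C))
  }
  a_x <- spec$a_x; a_y <- spec$a_y; bias <- spec$bias
  new_layer(function(x, training = FALSE) {
    h <- ag_dwconv2d(x, params$w_v, if (bias) params$b_v, dil_h = a_x, dil_w = 1L)
    ag_dwconv2d(h, params$w_h, if (bias) params$b_h, dil_h = 1L, dil_w = a_y)
  }, params = params, class = "depthwise_asym_conv")
}

# Plain dense conv layer (kh x kw), used by the model assembly.
conv_layer <- function(kh, kw, in_ch, out_ch, bias = TRUE,
                       dil_h = 1L, dil_w = 1L) {
  params <- list(w = ag_param(init_conv_w(kh, kw, in_ch, out_ch)))
  if (bias) params$b <- ag_param(numeric(out_ch))
  new_layer(function(x, training = FALSE) {
    ag_conv2d(x, params$w, params$b, dil_h = dil_h, dil_w = dil_w)
  }, params = params, class = "conv_layer")
}
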