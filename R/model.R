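# GISegNet assembly: an encoder of EDR blocks with 2x2 max-pool sampling, a
# hybrid-attention (EHAAC) bottleneck, a decoder of 2x2-stride transpose
# convolutions with additive skip connections and residual 3x3 refinement,
# and a 1x1 + sigmoid head producing a single-channel probability map at the
# input resolution.

#' Configuration of a GISegNet model
#'
#' The default width schedule `(24, 32, 71, 88)` was calibrated so that the
#' default 256x256x3 model counts exactly 648,457 trainable parameters.
#'
#' @param input_size Integer `(H, W, 3)`; `H` and `W` must be divisible by
#'   `2^depth`.
#' @param depth Number of encoder stages (EDR block + max-pool each).
#' @param widths Channel width per encoder stage; length must equal `depth`.
#' @param ehaac_rates Dilation rates of the bottleneck's spatial-attention
#'   branches.
#' @param ecam_reduction Reduction ratio of the bottleneck's channel gate.
#' @param out_rate Dilation rate of the bottleneck's fusion convolution.
#' @param head_threshold Probability threshold used by [predict_mask()].
#' @param skip_merge `"add"` (1x1-projected elementwise addition, default) or
#'   `"concat"` (channel concatenation before the refinement convolution).
#' @return A `gisegnet_config` object (also a plain list; JSON-serializable).
#' @export
gisegnet_config <- function(input_size = c(256L, 256L, 3L),
                            depth = 4L,
                            widths = c(24L, 32L, 71L, 88L),
                            ehaac_rates = c(1L, 6L, 12L, 18L),
                            ecam_reduction = 4L,
                            out_rate = 1L,
                            head_threshold = 0.5,
                            skip_merge = c("add", "concat")) {
  skip_merge <- match.arg(skip_merge)
  depth <- as.integer(depth)
  widths <- as.integer(widths)
  input_size <- as.integer(input_size)
  if (depth < 1L) abort("invalid config: `depth` must be >= 1")
  if (length(widths) != depth) {
    abort(sprintf("invalid config: length(widths) = %d must equal depth = %d",
                  length(widths), depth))
  }
  if (length(input_size) != 3L || input_size[3] != 3L) {
    abort("invalid config: `input_size` must be (H, W, 3)")
  }
  div <- 2L^depth
  if (input_size[1] %% div != 0L || input_size[2] %% div != 0L) {
    abort(sprintf(
      "invalid config: input H and W must be divisible by 2^depth = %d (got %d x %d)",
      div, input_size[1], input_size[2]))
  }
  if (!(head_threshold > 0 && head_threshold < 1)) {
    abort("invalid config: `head_threshold` must lie strictly in (0, 1)")
  }
  structure(
    list(input_size = input_size, depth = depth, widths = widths,
         ehaac_rates = as.integer(ehaac_rates),
         ecam_reduction = as.integer(ecam_reduction),
         out_rate = as.integer(out_rate),
         head_threshold = head_threshold, skip_merge = skip_merge),
    class = "gisegnet_config"
  )
}

# decoder stage: transpose-conv upsampling, skip merge, residual 3x3 refine
decoder_stage <- function(in_ch, width, skip_merge = "add") {
  children <- list(
    up = list(params = list(
      w = ag_param(init_conv_w(2L, 2L, in_ch, width)),
      b = ag_param(numeric(width))
    ))
  )
  class(children$up) <- "gi_layer"
  children$up$forward <- function(x, training = FALSE) {
    ag_convtr2(x, children$up$params$w, children$up$params$b)
  }
  refine_in <- if (skip_merge == "concat") 2L * width else width
  children$proj <- conv_layer(1L, 1L, width, width)
  children$refine <- conv_layer(3L, 3L, refine_in, width)
  params <- list(g = ag_param(rep(1, width)), be = ag_param(numeric(width)))
  states <- list(bn = new_bn_state(width))
  layer <- new_layer(NULL, params = params, children = children,
                     class = "decoder_stage")
  layer$states <- states
  layer$forward_pair <- function(x, skip, training = FALSE) {
    u <- children$up$forward(x, training = training)
    s <- children$proj$forward(skip, training = training)
    if (skip_merge == "add") {
      m <- ag_add(u, s)
      r <- ag_relu(ag_bn(children$refine$forward(m, training = training),
                         params$g, params$be, states$bn, training = training))
      ag_add(r, m)
    } else {
      m <- ag_concat_ch(u, s)
      r <- ag_relu(ag_bn(children$refine$forward(m, training = training),
                         params$g, params$be, states$bn, training = training))
      ag_add(r, u)
    }
  }
  layer
}

# channel concatenation for the optional concat skip merge
ag_concat_ch <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  v <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$value
  v[, , da[3] + seq_len(db[3]), ] <- b$value
  ag_node(v, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

#' Build a GISegNet model
#'
#' Encoder: `depth` stages of EDR block then 2x2 max-pool. Bottleneck: one
#' EHAAC module at the deepest width. Decoder: `depth` stages of 2x2-stride
#' transpose convolution, skip merge with the matching encoder EDR output,
#' and a residual 3x3 refinement convolution. Head: 1x1 convolution and
#' sigmoid, yielding an `(H, W, 1)` probability map. Weights are initialized
#' from the current RNG state; seed with [set.seed()] for reproducible
#' builds.
#'
#' @param config A [gisegnet_config()].
#' @return A `gisegnet_model` object.
#' @examples
#' set.seed(1)
#' tiny <- build_gisegnet(gisegnet_config(
#'   input_size = c(16L, 16L, 3L), depth = 1L, widths = 4L))
#' count_parameters(tiny)
#' @export
build_gisegnet <- function(config = gisegnet_config()) {
  stopifnot(inherits(config, "gisegnet_config"))
  d <- config$depth
  w <- config$widths
  enc <- vector("list", d)
  c_prev <- 3L
  for (i in seq_len(d)) {
    enc[[i]] <- build_edr(c_prev, w[i])
    c_prev <- w[i]
  }
  bottleneck <- build_ehaac(w[d], rates = config$ehaac_rates,
                            reduction = config$ecam_reduction,
                            out_rate = config$out_rate)
  dec <- vector("list", d)
  for (i in seq(d, 1L)) {
    in_ch <- if (i == d) w[d] else w[i + 1L]
    dec[[i]] <- decoder_stage(in_ch, w[i], config$skip_merge)
  }
  head_conv <- conv_layer(1L, 1L, w[1], 1L)
  children <- c(stats::setNames(enc, paste0("enc", seq_len(d))),
                list(bottleneck = bottleneck),
                stats::setNames(dec, paste0("dec", seq_len(d))),
                list(head = head_conv))
  net <- new_layer(NULL, children = children, class = "gisegnet_net")
  forward_logits <- function(x, training = FALSE) {
    skips <- vector("list", d)
    h <- x
    for (i in seq_len(d)) {
      skips[[i]] <- enc[[i]]$forward(h, training = training)
      h <- ag_maxpool2(skips[[i]])
    }
    h <- bottleneck$forward(h, training = training)
    for (i in seq(d, 1L)) {
      h <- dec[[i]]$forward_pair(h, skips[[i]], training = training)
    }
    head_conv$forward(h, training = training)
  }
  structure(
    list(net = net, config = config, forward_logits = forward_logits,
         params = layer_params(net)),
    class = "gisegnet_model"
  )
}

#' @export
print.gisegnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<gisegnet_model> input %dx%dx3, depth %d, widths (%s), %s parameters\n",
    cfg$input_size[1], cfg$input_size[2], cfg$depth,
    paste(cfg$widths, collapse = ", "),
    format(count_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

# forward pass on a plain batch array; returns sigmoid probabilities
gisegnet_probs <- function(model, images, training = FALSE) {
  b <- as_batch(images)
  logits <- model$forward_logits(ag_const(b$arr), training = training)$value
  p <- 1 / (1 + exp(-logits))
  if (b$had_batch) p else array(p, dim = dim(p)[1:3])
}

#' Predict a binary mask for one image
#'
#' Runs the model in inference mode and thresholds the sigmoid output.
#'
#' @param model A [build_gisegnet()] model.
#' @param image `H x W x 3` numeric array with values in `[0, 1]`.
#' @param threshold Probability threshold; defaults to the model config's
#'   `head_threshold`. A pixel is foreground iff its probability is >= the
#'   threshold.
#' @return `H x W` binary (0/1) matrix.
#' @export
predict_mask <- function(model, image, threshold = NULL) {
  stopifnot(inherits(model, "gisegnet_model"))
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    abort(sprintf("predict_mask expects an H x W x 3 image, got dims (%s)",
                  paste(d, collapse = ", ")))
  }
  threshold <- threshold %||% model$config$head_threshold
  p <- gisegnet_probs(model, image)
  mask <- (p[, , 1] >= threshold) * 1L
  matrix(as.integer(mask), d[1], d[2])
}

# ---- serialization ----------------------------------------------------------

# BN states of a layer tree, in deterministic traversal order
layer_states <- function(layer) {
  own <- if (!is.null(layer$states)) unname(layer$states) else list()
  c(own, unlist(lapply(layer$children, layer_states), use.names = FALSE))
}

#' Write / read a model config as JSON
#'
#' Round-trips every field of [gisegnet_config()] bit-exactly.
#'
#' @param config A [gisegnet_config()].
#' @param path File path.
#' @return `read_gisegnet_config()` returns the config; the writer returns
#'   `path` invisibly.
#' @export
write_gisegnet_config <- function(config, path) {
  stopifnot(inherits(config, "gisegnet_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_gisegnet_config
#' @export
read_gisegnet_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gisegnet_config(
    input_size = raw$input_size, depth = raw$depth, widths = raw$widths,
    ehaac_rates = raw$ehaac_rates, ecam_reduction = raw$ecam_reduction,
    out_rate = raw$out_rate, head_threshold = raw$head_threshold,
    skip_merge = raw$skip_merge
  )
}

#' Save / load model weights
#'
#' Single-file JSON checkpoint embedding the model config, every trainable
#' array (in build order) and the batch-normalization running statistics.
#' Because the architecture is a pure function of its config, loading
#' rebuilds the layer graph and restores values positionally.
#'
#' @param model A `gisegnet_model`.
#' @param path Checkpoint file path.
#' @return `load_gisegnet()` returns the restored model; the writer returns
#'   `path` invisibly.
#' @export
save_gisegnet <- function(model, path) {
  stopifnot(inherits(model, "gisegnet_model"))
  states <- layer_states(model$net)
  payload <- list(
    format = "gisegnet-checkpoint-1",
    config = unclass(model$config),
    params = lapply(model$params, function(p) {
      list(dim = dim(p$value) %||% length(p$value), data = as.vector(p$value))
    }),
    bn = lapply(states, function(s) list(rmean = s$rmean, rvar = s$rvar))
  )
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname save_gisegnet
#' @export
load_gisegnet <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- gisegnet_config(
    input_size = raw$config$input_size, depth = raw$config$depth,
    widths = raw$config$widths, ehaac_rates = raw$config$ehaac_rates,
    ecam_reduction = raw$config$ecam_reduction, out_rate = raw$config$out_rate,
    head_threshold = raw$config$head_threshold,
    skip_merge = raw$config$skip_merge
  )
  model <- build_gisegnet(cfg)
  if (length(raw$params$data) != length(model$params)) {
    abort("checkpoint does not match the rebuilt architecture")
  }
  for (k in seq_along(model$params)) {
    p <- model$params[[k]]
    d <- raw$params$dim[[k]]
    v <- raw$params$data[[k]]
    p$value <- if (length(d) > 1L) array(v, dim = d) else as.numeric(v)
  }
  states <- layer_states(model$net)
  for (k in seq_along(states)) {
    states[[k]]$rmean <- as.numeric(raw$bn$rmean[[k]])
    states[[k]]$rvar <- as.numeric(raw$bn$rvar[[k]])
  }
  model
}
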