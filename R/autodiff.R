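# Minimal reverse-mode automatic differentiation over numeric arrays.
# A node is an environment holding a value, an accumulated gradient, its
# parent nodes and a backward closure that maps the node's gradient to one
# gradient per parent. Nodes are ordered by a global creation counter; the
# backward sweep processes them in decreasing order, which is a valid
# topological order for any define-by-run graph.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_next_id <- function() {
  .ag$counter <- .ag$counter + 1L
  .ag$counter
}

ag_node <- function(value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$id <- ag_next_id()
  node$parents <- parents
  node$backward <- backward
  class(node) <- "ag_node"
  node
}

#' @noRd
ag_param <- function(value, name = NULL) {
  node <- ag_node(value)
  node$is_param <- TRUE
  node$name <- name
  node
}

ag_const <- function(value) ag_node(value)

is_ag_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (is_ag_node(x)) x$value else x

# Accumulate `g` into node$grad.
ag_accum <- function(node, g) {
  if (is.null(g)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Reverse sweep from `root`. `grad` defaults to 1 (scalar losses).
ag_backward <- function(root, grad = NULL) {
  if (is.null(grad)) grad <- array(1, dim = dim(root$value) %||% 1L)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  stack <- list(root)
  nodes <- vector("list", 256L)
  nn <- 0L
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  root$grad <- grad
  for (nd in nodes[ord]) {
    if (is.null(nd$backward) || is.null(nd$grad)) next
    pg <- nd$backward(nd$grad)
    for (k in seq_along(nd$parents)) ag_accum(nd$parents[[k]], pg[[k]])
  }
  invisible(root)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- elementwise ops --------------------------------------------------------

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_relu <- function(x) {
  mask <- x$value > 0
  ag_node(x$value * mask, list(x), function(g) list(g * mask))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

# ---- shape ops --------------------------------------------------------------

# Per-sample, per-channel spatial mean: H x W x C x N -> C x N matrix.
ag_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  v <- matrix(colMeans(matrix(x$value, nrow = hw)), d[3], d[4])
  ag_node(v, list(x), function(g) {
    gx <- array(rep(as.vector(g) / hw, each = hw), dim = d)
    list(gx)
  })
}

# Multiply an H x W x C x N map by a C x N channel gate (broadcast over H, W).
ag_scale_channels <- function(x, gate) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  gexp <- rep(as.vector(gate$value), each = hw)
  ag_node(array(x$value * gexp, dim = d), list(x, gate), function(g) {
    gx <- array(as.vector(g) * gexp, dim = d)
    gg <- matrix(colSums(matrix(as.vector(g) * as.vector(x$value), nrow = hw)), d[3], d[4])
    list(gx, gg)
  })
}

# Fully connected map on C x N column batches: value = W x + b.
ag_dense <- function(w, x, b = NULL) {
  wv <- w$value; xv <- x$value
  v <- wv %*% xv
  if (!is.null(b)) v <- v + b$value
  parents <- c(list(w, x), if (!is.null(b)) list(b))
  ag_node(v, parents, function(g) {
    out <- list(g %*% t(xv), t(wv) %*% g)
    if (!is.null(b)) out <- c(out, list(rowSums(g)))
    out
  })
}

# ---- batch normalization ----------------------------------------------------

# Normalizes each channel over (H, W, N). `state` carries running statistics
# for inference mode and is updated in place during training. The per-channel
# reductions and broadcasts run in compiled code.
ag_bn <- function(x, gamma, beta, state, training = FALSE,
                  eps = 1e-5, momentum = 0.1) {
  d <- dim(x$value)
  m <- d[1] * d[2] * d[4]
  if (training) {
    st <- cpp_chan_stats(x$value, d)
    mu <- st$sum / m
    var <- st$sumsq / m - mu^2
    var[var < 0] <- 0
    state$rmean <- (1 - momentum) * state$rmean + momentum * mu
    state$rvar <- (1 - momentum) * state$rvar + momentum * var * m / max(1, m - 1)
  } else {
    mu <- state$rmean
    var <- state$rvar
  }
  istd <- 1 / sqrt(var + eps)
  xhat <- cpp_chan_affine(x$value, d, istd, -mu * istd)
  v <- cpp_chan_affine(xhat, d, gamma$value, beta$value)
  ag_node(v, list(x, gamma, beta), function(g) {
    bw <- cpp_bn_bw(g, xhat, d, gamma$value, istd, training)
    list(bw$gx, bw$dgamma, bw$dbeta)
  })
}

new_bn_state <- function(C) {
  state <- new.env(parent = emptyenv())
  state$rmean <- numeric(C)
  state$rvar <- rep(1, C)
  state
}

# ---- convolution wrappers over the compiled kernels -------------------------

ag_conv2d <- function(x, w, b = NULL, dil_h = 1L, dil_w = 1L) {
  xv <- x$value; wv <- w$value
  xd <- dim(xv); wd <- dim(wv)
  bv <- if (is.null(b)) numeric(0) else b$value
  v <- cpp_conv2d_fw(xv, xd, wv, wd, bv, dil_h, dil_w)
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  ag_node(v, parents, function(g) {
    bw <- cpp_conv2d_bw(xv, xd, wv, wd, g, dil_h, dil_w, !is.null(b))
    out <- list(bw$gx, bw$gw)
    if (!is.null(b)) out <- c(out, list(bw$gb))
    out
  })
}

ag_dwconv2d <- function(x, w, b = NULL, dil_h = 1L, dil_w = 1L) {
  xv <- x$value; wv <- w$value
  xd <- dim(xv); wd <- dim(wv)
  bv <- if (is.null(b)) numeric(0) else b$value
  v <- cpp_dwconv2d_fw(xv, xd, wv, wd, bv, dil_h, dil_w)
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  ag_node(v, parents, function(g) {
    bw <- cpp_dwconv2d_bw(xv, xd, wv, wd, g, dil_h, dil_w, !is.null(b))
    out <- list(bw$gx, bw$gw)
    if (!is.null(b)) out <- c(out, list(bw$gb))
    out
  })
}

ag_maxpool2 <- function(x) {
  xd <- dim(x$value)
  fw <- cpp_maxpool2_fw(x$value, xd)
  ag_node(fw$y, list(x), function(g) list(cpp_maxpool2_bw(g, fw$idx, xd)))
}

ag_convtr2 <- function(x, w, b = NULL) {
  xv <- x$value; wv <- w$value
  xd <- dim(xv); wd <- dim(wv)
  bv <- if (is.null(b)) numeric(0) else b$value
  v <- cpp_convtr2_fw(xv, xd, wv, wd, bv)
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  ag_node(v, parents, function(g) {
    bw <- cpp_convtr2_bw(xv, xd, wv, wd, g, !is.null(b))
    out <- list(bw$gx, bw$gw)
    if (!is.null(b)) out <- c(out, list(bw$gb))
    out
  })
}

# ---- losses -----------------------------------------------------------------

# Numerically stable binary cross-entropy on pre-sigmoid logits.
ag_bce_logits <- function(logits, target) {
  z <- logits$value
  y <- if (is_ag_node(target)) target$value else target
  n <- length(z)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  ag_node(loss, list(logits), function(g) {
    list(array(as.numeric(g) * (1 / (1 + exp(-z)) - y) / n, dim = dim(z)))
  })
}

# ---- Adam optimizer ---------------------------------------------------------

adam_optimizer <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(params, function(p) {
    if (is.null(dim(p$value))) numeric(length(p$value)) else array(0, dim(p$value))
  })
  opt$v <- opt$m
  class(opt) <- "adam_optimizer"
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (k in seq_along(opt$params)) {
    p <- opt$params[[k]]
    if (is.null(p$grad)) next
    g <- p$grad
    opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * g
    opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[k]] / bc1
    vhat <- opt$v[[k]] / bc2
    upd <- p$value - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    if (is.null(dim(p$value))) dim(upd) <- NULL
    p$value <- upd
  }
  invisible(opt)
}
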