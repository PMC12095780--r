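# Independent brute-force oracles used across the suite. They are written
# as plain nested loops over pixel/tap indices, sharing no code with the
# package's compiled kernels.

# dense dilated 2-D convolution, "same" zero padding
oracle_conv2d <- function(x, w, b = NULL, dh = 1, dw = 1) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- d <- c(d, 1L)
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  wd <- dim(w); kh <- wd[1]; kw <- wd[2]; Cout <- wd[4]
  ph <- (kh - 1) * dh / 2; pw <- (kw - 1) * dw / 2
  y <- array(0, c(H, W, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (j in 1:W) for (i in 1:H) {
    acc <- if (is.null(b)) 0 else b[co]
    for (ci in 1:Cin) for (a in 1:kh) for (b2 in 1:kw) {
      ii <- i + (a - 1) * dh - ph
      jj <- j + (b2 - 1) * dw - pw
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        acc <- acc + x[ii, jj, ci, n] * w[a, b2, ci, co]
      }
    }
    y[i, j, co, n] <- acc
  }
  y
}

# asymmetric pair applied through the dense oracle (vertical then horizontal)
oracle_asym_pair <- function(x, w_v, b_v, w_h, b_h, a_x = 1, a_y = 1) {
  h <- oracle_conv2d(x, w_v, b_v, dh = a_x, dw = 1)
  oracle_conv2d(h, w_h, b_h, dh = 1, dw = a_y)
}

sigm <- function(z) 1 / (1 + exp(-z))

# spatial gate: sum over rate branches of sigmoid(d_i(F)) * d_i(F)
oracle_esam <- function(x, branches, rates) {
  out <- NULL
  for (k in seq_along(rates)) {
    br <- branches[[k]]
    d <- oracle_asym_pair(x, br$w_v, br$b_v, br$w_h, br$b_h,
                          a_x = rates[k], a_y = rates[k])
    term <- sigm(d) * d
    out <- if (is.null(out)) term else out + term
  }
  out
}

# channel gate: GAP -> two gated linear maps -> pointwise map -> broadcast
oracle_ecam <- function(x, w) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- d <- c(d, 1L)
  out <- array(0, d)
  for (n in seq_len(d[4])) {
    gap <- vapply(seq_len(d[3]), function(c) mean(x[, , c, n]), numeric(1))
    a1 <- sigm(as.vector(w$w1 %*% gap + w$b1))
    a2 <- sigm(as.vector(w$w2 %*% a1 + w$b2))
    g <- as.vector(w$v %*% a2 + w$bv)
    for (c in seq_len(d[3])) out[, , c, n] <- x[, , c, n] * g[c]
  }
  out
}

# extract the branch weights of a built esam layer for oracle use
esam_branch_weights <- function(esam_layer) {
  lapply(esam_layer$children, function(br) {
    list(w_v = br$params$w_v$value, b_v = br$params$b_v$value,
         w_h = br$params$w_h$value, b_h = br$params$b_h$value)
  })
}

ecam_weights_of <- function(ecam_layer) {
  p <- ecam_layer$params
  list(w1 = p$w1$value, b1 = p$b1$value, w2 = p$w2$value, b2 = p$b2$value,
       v = p$v$value, bv = p$bv$value)
}

# set every parameter of a layer tree to a constant (default zero)
set_all_params <- function(layer, value = 0) {
  for (p in gisegnet:::layer_params(layer)) {
    p$value <- array(value, dim = dim(p$value) %||% length(p$value))
    if (is.null(dim(p$value)) || length(dim(p$value)) == 1L) {
      p$value <- as.numeric(p$value)
    }
  }
  invisible(layer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mutual information between two discrete codings, direct definition
oracle_mi <- function(a, b) {
  ta <- table(a); tb <- table(b); tj <- table(a, b)
  n <- length(a)
  mi <- 0
  for (i in rownames(tj)) for (j in colnames(tj)) {
    pij <- tj[i, j] / n
    if (pij > 0) mi <- mi + pij * log(pij / ((ta[i] / n) * (tb[j] / n)))
  }
  unname(mi)
}

# greedy mRMR (difference criterion) written independently over pre-binned
# columns; ties resolved toward the lowest index
oracle_mrmr <- function(B, y, k) {
  d <- ncol(B)
  rel <- vapply(seq_len(d), function(j) oracle_mi(B[, j], y), numeric(1))
  sel <- integer(0)
  for (step in seq_len(k)) {
    crit <- rep(-Inf, d)
    for (j in setdiff(seq_len(d), sel)) {
      red <- if (length(sel) == 0) 0 else {
        mean(vapply(sel, function(s) oracle_mi(B[, j], B[, s]), numeric(1)))
      }
      crit[j] <- rel[j] - red
    }
    sel <- c(sel, which.max(crit))
  }
  sel
}

# tiny deterministic image batch for classification tests
tiny_images <- function(n, size = 32, seed = 1) {
  gisegnet:::with_seed(seed, {
    lapply(seq_len(n), function(i) array(runif(size * size * 3), c(size, size, 3)))
  })
}
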