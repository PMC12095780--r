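# Class-structured synthetic feature matrices emulating per-extractor
# feature sets: informative columns (class-conditional Gaussians),
# exact-duplicate columns (for redundancy-selection tests) and pure-noise
# columns. All extractors share labels and sample order. In fusion-synergy
# mode one extractor's informative columns separate only classes 0-3 and
# another's only classes 4-7, so fusing the two is provably better than
# either alone.

#' Parameters of the synthetic feature generator
#'
#' @param n_per_class Samples per class.
#' @param n_classes Number of classes (default 8, labelled 0..7).
#' @param dims_per_extractor Named integer vector of output dimensions,
#'   defaulting to the extractor contracts:
#'   deit3_base_p16 = 768, maxvit_base = 768, swin_base_p4w7 = 1024,
#'   vit_base_p16 = 768.
#' @param informative_frac,duplicate_frac Fractions of columns that carry
#'   class signal and that exactly duplicate an informative column.
#' @param noise_sigma Standard deviation of all columns' noise.
#' @param class_sep Effect size: class means are drawn with standard
#'   deviation `class_sep * noise_sigma`; 0 gives chance-level data.
#' @param synergy Fusion-synergy mode: `deit3_base_p16` informative columns
#'   separate only classes 0-3, `swin_base_p4w7` only classes 4-7.
#' @param seed Integer seed.
#' @return A `feature_gen_params` object.
#' @export
feature_gen_params <- function(n_per_class = 25L, n_classes = 8L,
                               dims_per_extractor = NULL,
                               informative_frac = 0.05, duplicate_frac = 0.05,
                               noise_sigma = 1, class_sep = 2,
                               synergy = FALSE, seed = 1L) {
  if (is.null(dims_per_extractor)) {
    dims_per_extractor <- c(deit3_base_p16 = 768L, maxvit_base = 768L,
                            swin_base_p4w7 = 1024L, vit_base_p16 = 768L)
  }
  if (informative_frac < 0 || informative_frac > 1 ||
      duplicate_frac < 0 || duplicate_frac > 1) {
    abort("invalid params: fractions must lie in [0, 1]")
  }
  for (nm in names(dims_per_extractor)) {
    d <- dims_per_extractor[[nm]]
    if (round(d * informative_frac) + round(d * duplicate_frac) > d) {
      abort(sprintf("invalid params: %s has too few dimensions (%d) for the requested fractions", nm, d))
    }
    if (round(d * duplicate_frac) > round(d * informative_frac)) {
      abort("invalid params: duplicate columns need at least as many informative sources")
    }
  }
  structure(
    list(n_per_class = as.integer(n_per_class),
         n_classes = as.integer(n_classes),
         dims_per_extractor = dims_per_extractor,
         informative_frac = informative_frac,
         duplicate_frac = duplicate_frac,
         noise_sigma = noise_sigma, class_sep = class_sep,
         synergy = isTRUE(synergy), seed = as.integer(seed)),
    class = "feature_gen_params"
  )
}

# construct a feature tibble with origin / role metadata attributes
feature_matrix <- function(X, y, origin) {
  colnames(X) <- sprintf("f_%04d", seq_len(ncol(X)))
  fm <- as_tibble(as.data.frame(X))
  fm$label <- as.integer(y)
  attr(fm, "origin") <- origin
  class(fm) <- c("gi_features", class(fm))
  fm
}

#' Columns of a feature tibble (excluding the label)
#' @param fm A feature tibble.
#' @return Numeric matrix `n x d`.
#' @export
feature_values <- function(fm) {
  as.matrix(fm[setdiff(names(fm), "label")])
}

#' Generate synthetic per-extractor feature matrices
#'
#' @param params A [feature_gen_params()].
#' @return Named list of feature tibbles (one per extractor), each carrying
#'   `origin`, `roles` (informative / duplicate / noise per column) and
#'   `duplicate_of` attributes. All share the `label` column and row order.
#' @export
gen_feature_dataset <- function(params) {
  stopifnot(inherits(params, "feature_gen_params"))
  n <- params$n_per_class * params$n_classes
  y <- rep(seq_len(params$n_classes) - 1L, each = params$n_per_class)
  with_seed(params$seed, {
    perm <- sample.int(n)  # shared sample order, classes interleaved
    y <- y[perm]
    out <- list()
    for (nm in names(params$dims_per_extractor)) {
      d <- as.integer(params$dims_per_extractor[[nm]])
      n_inf <- round(d * params$informative_frac)
      n_dup <- round(d * params$duplicate_frac)
      X <- matrix(rnorm(n * d, sd = params$noise_sigma), n, d)
      roles <- rep("noise", d)
      dup_of <- rep(NA_integer_, d)
      if (n_inf > 0) {
        active <- seq_len(params$n_classes)
        if (params$synergy && nm == "deit3_base_p16") active <- 1:4
        if (params$synergy && nm == "swin_base_p4w7") active <- 5:8
        mu <- matrix(0, n_inf, params$n_classes)
        mu[, active] <- params$class_sep * params$noise_sigma *
          matrix(rnorm(n_inf * length(active)), n_inf)
        for (j in seq_len(n_inf)) {
          X[, j] <- X[, j] + mu[j, y + 1L]
        }
        roles[seq_len(n_inf)] <- "informative"
      }
      if (n_dup > 0) {
        src <- sample(seq_len(n_inf), n_dup)
        for (k in seq_len(n_dup)) {
          X[, n_inf + k] <- X[, src[k]]
        }
        roles[n_inf + seq_len(n_dup)] <- "duplicate"
        dup_of[n_inf + seq_len(n_dup)] <- src
      }
      fm <- feature_matrix(X, y, origin = rep(nm, d))
      attr(fm, "roles") <- roles
      attr(fm, "duplicate_of") <- dup_of
      out[[nm]] <- fm
    }
    out
  })
}
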