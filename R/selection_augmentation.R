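# --- recursive feature elimination ---------------------------------------

# Internal ranker: one-vs-rest ridge (regularized least squares) on
# standardized features; importance = row sum of squared coefficients.
ridge_importance <- function(X, y, lambda = 1e-2) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Yh <- stats::model.matrix(~ 0 + factor(y))
  p <- ncol(Z)
  W <- solve(crossprod(Z) + lambda * nrow(Z) * diag(p), crossprod(Z, Yh))
  rowSums(W^2)
}

#' Recursive feature elimination
#'
#' Iteratively fits the internal ranker (an L2-regularized one-vs-rest linear
#' classifier on standardized features) on the surviving features and drops
#' the lowest-ranked `ceiling(5%)` per iteration until `n_keep` remain. Ties
#' are broken by dropping the higher column index, so one of two duplicated
#' columns deterministically survives the other.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y class labels (>= 2 classes).
#' @param n_keep number of features to retain (`1 <= n_keep <= ncol(X)`).
#' @param step_frac fraction of surviving features dropped per iteration
#'   (default 0.05).
#' @param lambda ridge penalty of the internal ranker.
#' @return An object of class `"rfe_selection"`: `kept_indices` (ascending),
#'   `ranking` (feature indices from first-eliminated to last-surviving) and
#'   `estimator_config`.
#' @export
rfe_select <- function(X, y, n_keep, step_frac = 0.05, lambda = 1e-2) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stopf("need >= 2 classes in y")
  if (n_keep <= 0) stopf("parameter error: n_keep must be positive")
  if (n_keep > ncol(X)) stopf("parameter error: n_keep > n_features")
  remaining <- seq_len(ncol(X))
  eliminated <- integer(0)
  while (length(remaining) > n_keep) {
    imp <- ridge_importance(X[, remaining, drop = FALSE], y, lambda)
    n_drop <- min(ceiling(step_frac * length(remaining)),
                  length(remaining) - n_keep)
    # lowest importance first; ties resolved toward the higher column index
    ord <- order(imp, -remaining)
    drop <- remaining[ord[seq_len(n_drop)]]
    eliminated <- c(eliminated, drop)
    remaining <- setdiff(remaining, drop)
  }
  structure(list(kept_indices = sort(remaining),
                 ranking = c(eliminated, sort(remaining)),
                 estimator_config = list(estimator = "ridge_ovr",
                                         lambda = lambda,
                                         step_frac = step_frac)),
            class = "rfe_selection")
}

#' @export
print.rfe_selection <- function(x, ...) {
  cat(sprintf("<rfe_selection> kept %d features: %s%s\n",
              length(x$kept_indices),
              paste(utils::head(x$kept_indices, 10), collapse = ", "),
              if (length(x$kept_indices) > 10) ", ..." else ""))
  invisible(x)
}

# --- genetic-algorithm augmentation --------------------------------------

#' Middle-third crossover of two feature vectors
#'
#' Splits both vectors into three (near-)equal parts at `floor(L/3)` and
#' `L - floor(L/3)` and swaps the central part: the child is
#' `[a_first, b_middle, a_last]`.
#'
#' @param a,b numeric vectors of equal length `L >= 3`.
#' @return The hybridized child vector.
#' @export
#' @examples
#' ga_crossover(1:6, 7:12)  # 1 2 9 10 5 6
ga_crossover <- function(a, b) {
  L <- length(a)
  if (length(b) != L) stopf("shape error: parent lengths %d != %d", L, length(b))
  if (L < 3) stopf("shape error: vectors must have length >= 3")
  cut <- L %/% 3
  c(a[seq_len(cut)], b[(cut + 1):(L - cut)], a[(L - cut + 1):L])
}

#' Genetic-algorithm data augmentation
#'
#' For every original feature vector, generates `n_generations` offspring,
#' each by crossing the original with a freshly sampled partner from the
#' remaining vectors (never itself; same-class by default so the inherited
#' first-parent label stays truthful). The augmented set holds the originals
#' followed by all offspring: `(1 + n_generations) * n` rows, with per-class
#' counts scaled by exactly the same factor. Classes with a single vector are
#' copied without crossover, with a warning. Fully reproducible given `seed`.
#'
#' @param X numeric feature matrix (rows = vectors).
#' @param y labels, one per row.
#' @param n_generations offspring per original (default 10).
#' @param seed integer seed.
#' @param same_class restrict partners to the first parent's class
#'   (default `TRUE`).
#' @param chained if `TRUE`, each generation crosses the previous offspring
#'   rather than the original.
#' @return An object of class `"augmented_dataset"`: `X`, `y` and a
#'   `provenance` data frame `(parent_index, partner_index, generation)` per
#'   offspring (`NA` partner for copied singletons).
#' @export
ga_augment <- function(X, y, n_generations = 10, seed = NULL,
                       same_class = TRUE, chained = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == length(y))
  out <- with_seed(seed, {
    kids <- vector("list", n * n_generations)
    prov <- matrix(NA_integer_, n * n_generations, 3,
                   dimnames = list(NULL, c("parent_index", "partner_index",
                                           "generation")))
    warned <- character(0)
    k <- 0L
    for (g in seq_len(n_generations)) {
      for (i in seq_len(n)) {
        pool <- if (same_class) setdiff(which(y == y[i]), i) else setdiff(seq_len(n), i)
        k <- k + 1L
        if (!length(pool)) {
          if (!as.character(y[i]) %in% warned) {
            warnf("class '%s' has a single vector; copied without crossover", y[i])
            warned <- c(warned, as.character(y[i]))
          }
          kids[[k]] <- X[i, ]
          prov[k, ] <- c(i, NA_integer_, g)
        } else {
          j <- pool[sample.int(length(pool), 1)]
          base <- if (chained && g > 1) kids[[k - n]] else X[i, ]
          kids[[k]] <- ga_crossover(base, X[j, ])
          prov[k, ] <- c(i, j, g)
        }
      }
    }
    list(kids = kids, prov = prov)
  })
  structure(list(X = rbind(X, do.call(rbind, out$kids)),
                 y = c(y, rep(y, n_generations)),
                 provenance = as.data.frame(out$prov),
                 n_originals = n, n_generations = n_generations),
            class = "augmented_dataset")
}

#' @export
print.augmented_dataset <- function(x, ...) {
  cat(sprintf("<augmented_dataset> %d originals + %d offspring = %d vectors\n",
              x$n_originals, nrow(x$X) - x$n_originals, nrow(x$X)))
  invisible(x)
}
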