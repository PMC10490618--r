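# Deep neural decision forest: a fully connected embedding network feeding an
# ensemble of soft (sigmoid-routed) decision trees with softmax leaf class
# distributions, trained jointly by minibatch Adam on the negative
# log-likelihood of the tree-averaged prediction.

#' Configuration of a deep neural decision forest
#'
#' The architecture fixes only the published skeleton — an input feature
#' vector (740-dimensional when the full dual-bank layout is used), a
#' 128-dimensional embedding, and a decision forest on top. Everything else
#' is tunable: two rectifier hidden layers (512, 256) before the linear
#' embedding, 10 trees of depth 6, Adam with minibatches.
#'
#' @param input_dim number of input features (taken from the data at fit
#'   time when `NULL`).
#' @param embed_dim embedding width (default 128).
#' @param hidden_layers integer vector of hidden widths (default `c(512, 256)`).
#' @param n_trees trees in the forest (default 10).
#' @param tree_depth depth of each tree; `2^depth` leaves (default 6).
#' @param epochs,batch_size,learning_rate optimizer settings.
#' @param seed integer seed for reproducible initialization and batching.
#' @param class_weights `"none"` or `"balanced"` (inverse-frequency loss
#'   weights).
#' @param standardize center/scale features with train-split statistics.
#' @return A list of class `"dndf_config"`.
#' @export
dndf_config <- function(input_dim = NULL, embed_dim = 128,
                        hidden_layers = c(512, 256), n_trees = 10,
                        tree_depth = 6, epochs = 40, batch_size = 64,
                        learning_rate = 1e-3, seed = 1,
                        class_weights = c("none", "balanced"),
                        standardize = TRUE) {
  class_weights <- match.arg(class_weights)
  cfg <- list(input_dim = input_dim, embed_dim = embed_dim,
              hidden_layers = hidden_layers, n_trees = n_trees,
              tree_depth = tree_depth, epochs = epochs, batch_size = batch_size,
              learning_rate = learning_rate, seed = seed,
              class_weights = class_weights, standardize = standardize)
  num <- unlist(cfg[c("embed_dim", "n_trees", "tree_depth", "epochs",
                      "batch_size", "learning_rate")])
  if (any(num <= 0)) stopf("config error: all dimensions/settings must be positive")
  structure(cfg, class = "dndf_config")
}

# leaf-path bookkeeping shared by all trees of a given depth:
# heap-ordered internal nodes, and leaf-by-node membership of left/right
# subtrees (used for both routing products and their gradients)
tree_topology <- function(depth) {
  n_leaves <- 2^depth
  n_internal <- n_leaves - 1
  L <- matrix(0, n_leaves, n_internal)
  R <- matrix(0, n_leaves, n_internal)
  for (j in seq_len(n_leaves)) {
    for (l in 0:(depth - 1)) {
      node <- 2^l + (j - 1) %/% 2^(depth - l)
      left <- ((j - 1) %/% 2^(depth - l - 1)) %% 2 == 0
      if (left) L[j, node] <- 1 else R[j, node] <- 1
    }
  }
  list(n_leaves = n_leaves, n_internal = n_internal, L = L, R = R)
}

#' Build an untrained deep neural decision forest
#'
#' Seeded initialization: He-scaled Gaussian weights for the rectifier
#' layers, small Gaussian routing weights, and zero leaf parameters, so every
#' untrained leaf distribution is exactly uniform over classes.
#'
#' @param cfg a [dndf_config()] with `input_dim` set.
#' @param classes character vector of class labels.
#' @return An object of class `"dndf"` with `trained = FALSE`.
#' @export
dndf_build <- function(cfg, classes) {
  if (is.null(cfg$input_dim)) stopf("config error: input_dim must be set to build")
  n_classes <- length(classes)
  if (n_classes < 2) stopf("config error: need >= 2 classes")
  topo <- tree_topology(cfg$tree_depth)
  with_seed(cfg$seed, {
    dims <- c(cfg$input_dim, cfg$hidden_layers, cfg$embed_dim)
    W <- list(); b <- list()
    for (l in seq_len(length(dims) - 1)) {
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
                       dims[l], dims[l + 1])
      b[[l]] <- numeric(dims[l + 1])
    }
    Wr <- lapply(seq_len(cfg$n_trees), function(t)
      matrix(stats::rnorm(cfg$embed_dim * topo$n_internal,
                          sd = 1 / sqrt(cfg$embed_dim)),
             cfg$embed_dim, topo$n_internal))
    br <- lapply(seq_len(cfg$n_trees), function(t) numeric(topo$n_internal))
    theta <- lapply(seq_len(cfg$n_trees), function(t)
      matrix(0, topo$n_leaves, n_classes))
    structure(list(cfg = cfg, classes = classes, topo = topo,
                   params = list(W = W, b = b, Wr = Wr, br = br, theta = theta),
                   scale = NULL, trained = FALSE, loss_trace = NULL),
              class = "dndf")
  })
}

softmax_rows <- function(M) {
  E <- exp(M - apply(M, 1, max))
  E / rowSums(E)
}

# forward pass; returns activations needed for backprop when keep = TRUE
dndf_forward <- function(model, X, keep = FALSE) {
  p <- model$params
  H <- list(X)
  nl <- length(p$W)
  for (l in seq_len(nl)) {
    A <- sweep(H[[l]] %*% p$W[[l]], 2, p$b[[l]], "+")
    H[[l + 1]] <- if (l < nl) pmax(A, 0) else A   # linear embedding output
  }
  Z <- H[[nl + 1]]
  B <- nrow(Z)
  depth <- model$cfg$tree_depth
  trees <- lapply(seq_len(model$cfg$n_trees), function(t) {
    dmat <- 1 / (1 + exp(-sweep(Z %*% p$Wr[[t]], 2, p$br[[t]], "+")))
    M <- matrix(1, B, 1)
    for (l in 0:(depth - 1)) {
      nodes <- (2^l):(2^(l + 1) - 1)
      D <- dmat[, nodes, drop = FALSE]
      K <- ncol(M)
      M2 <- matrix(0, B, 2 * K)
      M2[, seq(1, 2 * K, 2)] <- M * D
      M2[, seq(2, 2 * K, 2)] <- M * (1 - D)
      M <- M2
    }
    pi_t <- softmax_rows(p$theta[[t]])
    list(dmat = dmat, mu = M, pi = pi_t)
  })
  P <- Reduce(`+`, lapply(trees, function(tr) tr$mu %*% tr$pi)) / model$cfg$n_trees
  if (keep) list(P = P, H = H, Z = Z, trees = trees) else list(P = P)
}

adam_new <- function() list(m = NULL, v = NULL, t = 0)
adam_step <- function(state, g, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(state$m)) { state$m <- g * 0; state$v <- g * 0 }
  state$t <- state$t + 1
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g^2
  mh <- state$m / (1 - b1^state$t)
  vh <- state$v / (1 - b2^state$t)
  state$delta <- lr * mh / (sqrt(vh) + eps)
  state
}

#' Train a deep neural decision forest
#'
#' Joint minimization of the negative log-likelihood of the tree-averaged
#' prediction by minibatch Adam: sigmoid routing gates on linear projections
#' of the embedding, softmax leaf distributions, all parameters updated
#' together (no alternating leaf/route optimization). Reproducible given the
#' config seed.
#'
#' @param model an untrained or trained `"dndf"` from [dndf_build()].
#' @param X feature matrix with `cfg$input_dim` columns.
#' @param y labels drawn from `model$classes`.
#' @return The trained model, with `$loss_trace` (mean NLL per epoch).
#' @export
dndf_train <- function(model, X, y) {
  X <- as.matrix(X)
  cfg <- model$cfg
  if (ncol(X) != cfg$input_dim)
    stopf("shape error: X has %d columns, model expects %d", ncol(X), cfg$input_dim)
  if (!all(y %in% model$classes)) stopf("label(s) outside the model's classes")
  if (cfg$standardize) {
    mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
    model$scale <- list(mu = mu, sd = sdv)
    X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  }
  yi <- match(y, model$classes)
  n <- nrow(X)
  n_classes <- length(model$classes)
  wts <- if (cfg$class_weights == "balanced") {
    cw <- n / (n_classes * tabulate(yi, n_classes))
    cw[yi]
  } else rep(1, n)
  topo <- model$topo
  opt <- list()
  trace <- numeric(cfg$epochs)
  model <- with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      ep_loss <- 0; ep_n <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- yi[idx]
        wb <- wts[idx]
        fw <- dndf_forward(model, Xb, keep = TRUE)
        Py <- pmax(fw$P[cbind(seq_along(idx), yb)], 1e-12)
        loss <- -sum(wb * log(Py)) / sum(wb)
        if (!is.finite(loss)) stopf("NaN loss at epoch %d; aborting", ep)
        ep_loss <- ep_loss + loss * length(idx); ep_n <- ep_n + length(idx)
        grads <- dndf_backward(model, fw, yb, wb, Py)
        for (nm in names(grads)) {
          if (is.null(opt[[nm]])) opt[[nm]] <- adam_new()
          opt[[nm]] <- adam_step(opt[[nm]], grads[[nm]], cfg$learning_rate)
          model$params <- assign_param(model$params, nm, opt[[nm]]$delta)
        }
      }
      trace[ep] <- ep_loss / ep_n
    }
    model
  })
  model$trained <- TRUE
  model$loss_trace <- trace
  model
}

# parameter names are "W.1", "Wr.3", "theta.2", ...; subtract the Adam delta
assign_param <- function(params, nm, delta) {
  parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
  grp <- parts[1]; i <- as.integer(parts[2])
  params[[grp]][[i]] <- params[[grp]][[i]] - delta
  params
}

dndf_backward <- function(model, fw, yb, wb, Py) {
  cfg <- model$cfg
  topo <- model$topo
  p <- model$params
  B <- length(yb)
  sw <- sum(wb)
  n_classes <- length(model$classes)
  Y1 <- matrix(0, B, n_classes); Y1[cbind(seq_len(B), yb)] <- 1
  grads <- list()
  gZ <- matrix(0, B, cfg$embed_dim)
  for (t in seq_len(cfg$n_trees)) {
    tr <- fw$trees[[t]]
    # g[i,l] = w_i * mu_il * pi_l(y_i) / (T * P_i(y_i))
    g <- wb * tr$mu * t(tr$pi[, yb, drop = FALSE]) /
      (cfg$n_trees * Py)
    s <- colSums(g)
    A <- crossprod(g, Y1)                       # leaves x classes
    grads[[paste0("theta.", t)]] <- -(A - s * tr$pi) / sw
    GL <- g %*% topo$L
    GR <- g %*% topo$R
    gF <- -(GL * (1 - tr$dmat) - GR * tr$dmat) / sw
    grads[[paste0("Wr.", t)]] <- crossprod(fw$Z, gF)
    grads[[paste0("br.", t)]] <- colSums(gF)
    gZ <- gZ + gF %*% t(p$Wr[[t]])
  }
  nl <- length(p$W)
  G <- gZ
  for (l in nl:1) {
    grads[[paste0("W.", l)]] <- crossprod(fw$H[[l]], G)
    grads[[paste0("b.", l)]] <- colSums(G)
    if (l > 1) G <- (G %*% t(p$W[[l]])) * (fw$H[[l]] > 0)
  }
  grads
}

#' Fit a deep neural decision forest
#'
#' Convenience fitter: builds and trains in one call. `dndf` is generic with
#' a default matrix interface and a formula method.
#'
#' @param x feature matrix (rows = samples), or a formula.
#' @param y labels (factor or character).
#' @param ... settings forwarded to [dndf_config()].
#' @return A trained object of class `"dndf"`.
#' @export
dndf <- function(x, ...) UseMethod("dndf")

#' @rdname dndf
#' @export
dndf.default <- function(x, y, ...) {
  x <- as.matrix(x)
  cfg <- dndf_config(input_dim = ncol(x), ...)
  classes <- sort(unique(as.character(y)))
  model <- dndf_build(cfg, classes)
  dndf_train(model, x, as.character(y))
}

#' @rdname dndf
#' @param data data frame holding the formula's variables.
#' @export
dndf.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- as.character(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  dndf.default(X, y, ...)
}

#' Predict from a deep neural decision forest
#'
#' @param object a trained `"dndf"`.
#' @param newdata feature matrix with `input_dim` columns.
#' @param type `"class"` for labels (argmax, ties to the lowest class
#'   index) or `"prob"` for the class-distribution matrix (rows sum to 1).
#' @param ... unused.
#' @return Character labels or a probability matrix.
#' @export
predict.dndf <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained)) stopf("state error: model is not trained")
  X <- as.matrix(newdata)
  if (ncol(X) != object$cfg$input_dim)
    stopf("shape error: newdata has %d columns, model expects %d",
          ncol(X), object$cfg$input_dim)
  if (!is.null(object$scale))
    X <- sweep(sweep(X, 2, object$scale$mu), 2, object$scale$sd, "/")
  P <- dndf_forward(object, X)$P
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  object$classes[apply(P, 1, which.max)]
}

#' @rdname predict.dndf
#' @param model a trained `"dndf"`.
#' @param X feature matrix.
#' @export
predict_proba <- function(model, X) predict(model, X, type = "prob")

#' @export
print.dndf <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<dndf> %s, %d -> [%s] -> %d -> %d trees (depth %d), %d classes\n",
              if (x$trained) "trained" else "untrained", cfg$input_dim,
              paste(cfg$hidden_layers, collapse = ", "), cfg$embed_dim,
              cfg$n_trees, cfg$tree_depth, length(x$classes)))
  if (x$trained)
    cat(sprintf("  final training NLL: %.4f after %d epochs\n",
                utils::tail(x$loss_trace, 1), cfg$epochs))
  invisible(x)
}

#' @export
summary.dndf <- function(object, ...) {
  print(object)
  n_par <- sum(vapply(unlist(object$params, recursive = FALSE), length, 0L))
  cat(sprintf("  parameters: %d\n  classes: %s\n", n_par,
              paste(object$classes, collapse = ", ")))
  invisible(object)
}

#' @export
plot.dndf <- function(x, ...) {
  if (is.null(x$loss_trace)) stopf("nothing to plot: model is untrained")
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "training NLL", main = "dndf loss trace", ...)
  invisible(x)
}

# --- evaluation ----------------------------------------------------------

#' Classification metrics from labels
#'
#' @param truth,pred label vectors.
#' @param labels the full class set (default: union of both).
#' @return List with `confusion` (rows = true class), `confusion_norm`
#'   (row-normalized), per-class `precision`, `recall`, `f1`, plus
#'   `accuracy`, `macro_accuracy` (mean per-class recall) and `macro_f1`.
#' @export
classification_metrics <- function(truth, pred, labels = NULL) {
  labels <- labels %||% sort(unique(c(truth, pred)))
  cm <- table(factor(truth, labels), factor(pred, labels))
  cm <- matrix(as.numeric(cm), length(labels), length(labels),
               dimnames = list(true = labels, pred = labels))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  rows_present <- rowSums(cm) > 0
  list(confusion = cm,
       confusion_norm = cm / pmax(rowSums(cm), 1),
       precision = prec, recall = rec, f1 = f1,
       accuracy = sum(tp) / sum(cm),
       macro_accuracy = mean(rec[rows_present]),
       macro_f1 = mean(f1[rows_present]))
}

#' Evaluate a trained model on labeled data
#'
#' @param model a trained `"dndf"`.
#' @param X feature matrix.
#' @param y true labels; must be drawn from the model's training classes.
#' @return See [classification_metrics()].
#' @export
dndf_evaluate <- function(model, X, y) {
  if (!all(y %in% model$classes))
    stopf("evaluation error: label(s) absent from training classes: %s",
          paste(setdiff(y, model$classes), collapse = ", "))
  classification_metrics(as.character(y), predict(model, X), model$classes)
}

#' Stratified k-fold cross-validation driver
#'
#' Splits before any augmentation (augmentation, when given, is applied to
#' the training split only, so offspring never leak into evaluation), trains
#' one model per fold, and aggregates fold metrics.
#'
#' @param X feature matrix.
#' @param y labels.
#' @param folds number of folds (default 10).
#' @param seed seed controlling fold assignment.
#' @param train_fn function `(X_train, y_train) -> model` (e.g. a [dndf()]
#'   wrapper); the model must support `predict(model, X)`.
#' @param augment_fn optional function `(X_train, y_train) -> list(X, y)`
#'   applied to each training split.
#' @return List with `fold_metrics` (one [classification_metrics()] result
#'   per fold), and aggregate `accuracy` / `macro_accuracy` (means over
#'   folds).
#' @export
cross_validate <- function(X, y, folds = 10, seed = 1, train_fn,
                           augment_fn = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  fold_id <- with_seed(seed, {
    id <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  res <- lapply(seq_len(folds), function(k) {
    tr <- fold_id != k
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (!is.null(augment_fn)) {
      aug <- augment_fn(Xtr, ytr)
      Xtr <- aug$X; ytr <- aug$y
    }
    model <- train_fn(Xtr, ytr)
    classification_metrics(y[!tr], predict(model, X[!tr, , drop = FALSE]),
                           sort(unique(y)))
  })
  list(fold_metrics = res,
       accuracy = mean(vapply(res, `[[`, 0, "accuracy")),
       macro_accuracy = mean(vapply(res, `[[`, 0, "macro_accuracy")),
       folds = folds)
}
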