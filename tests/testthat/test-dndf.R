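make_blobs <- function(n = 400, sep = 0.4, sd = 0.1, seed = 11) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n / 2, 0, sd), rnorm(n / 2, 0, sd)),
             cbind(rnorm(n / 2, sep, sd), rnorm(n / 2, sep, sd)))
  list(X = X, y = rep(c("lo", "hi"), each = n / 2))
}

small_cfg <- function(...) {
  dndf_config(input_dim = 2, embed_dim = 16, hidden_layers = c(32),
              n_trees = 4, tree_depth = 3, epochs = 50, seed = 2, ...)
}

test_that("build produces a seeded, uniform-leaf, untrained model", {
  cfg <- dndf_config(input_dim = 740, embed_dim = 128, seed = 7)
  m <- dndf_build(cfg, c("a", "b", "c"))
  # embedding output width is the configured 128
  expect_equal(ncol(m$params$W[[length(m$params$W)]]), 128)
  # untrained leaves are exactly uniform
  pi1 <- exp(m$params$theta[[1]]) / rowSums(exp(m$params$theta[[1]]))
  expect_true(all(abs(pi1 - 1 / 3) < 1e-12))
  expect_false(m$trained)
  m2 <- dndf_build(cfg, c("a", "b", "c"))
  expect_identical(m$params, m2$params)
  expect_error(dndf_build(dndf_config(input_dim = NULL), c("a", "b")),
               "config error")
  expect_error(dndf_config(epochs = -1), "config error")
})

test_that("routing probabilities over leaves telescope to 1", {
  blobs <- make_blobs()
  m <- dndf_build(small_cfg(), c("hi", "lo"))
  fw <- imupipe:::dndf_forward(m, blobs$X, keep = TRUE)
  for (tr in fw$trees)
    expect_lt(max(abs(rowSums(tr$mu) - 1)), 1e-6)
  expect_lt(max(abs(rowSums(fw$P) - 1)), 1e-6)
})

test_that("training separates Gaussian blobs and is reproducible", {
  blobs <- make_blobs()
  fit <- dndf(blobs$X, blobs$y, embed_dim = 16, hidden_layers = c(32),
              n_trees = 4, tree_depth = 3, epochs = 50, seed = 2)
  expect_gte(mean(predict(fit, blobs$X) == blobs$y), 0.99)
  # smoothed loss trend is non-increasing
  sm <- stats::filter(fit$loss_trace, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(utils::tail(sm, 1), sm[1])
  fit2 <- dndf(blobs$X, blobs$y, embed_dim = 16, hidden_layers = c(32),
               n_trees = 4, tree_depth = 3, epochs = 50, seed = 2)
  expect_identical(fit$params, fit2$params)
  expect_equal(fit$loss_trace, fit2$loss_trace)
})

test_that("shuffled labels give chance-level held-out accuracy", {
  blobs <- make_blobs(n = 400)
  set.seed(31)
  y_shuf <- sample(blobs$y)
  tr <- c(1:150, 201:350)
  fit <- dndf(blobs$X[tr, ], y_shuf[tr], embed_dim = 8, hidden_layers = c(16),
              n_trees = 3, tree_depth = 3, epochs = 20, seed = 5)
  acc <- mean(predict(fit, blobs$X[-tr, ]) == y_shuf[-tr])
  n_test <- length(y_shuf[-tr])
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n_test))
})

test_that("prediction distributions are normalized and argmax-consistent", {
  blobs <- make_blobs(n = 200)
  fit <- dndf(blobs$X, blobs$y, embed_dim = 8, hidden_layers = c(16),
              n_trees = 3, tree_depth = 2, epochs = 10, seed = 4)
  P <- predict_proba(fit, blobs$X)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-6)
  expect_identical(predict(fit, blobs$X),
                   colnames(P)[apply(P, 1, which.max)])
  expect_error(predict(dndf_build(small_cfg(), c("a", "b")), blobs$X),
               "state error")
  expect_error(predict(fit, blobs$X[, 1, drop = FALSE]), "shape error")
})

test_that("a depth-1 tree with zero routing weight mixes its leaves 50/50", {
  cfg <- dndf_config(input_dim = 2, embed_dim = 4, hidden_layers = c(4),
                     n_trees = 1, tree_depth = 1, seed = 1)
  m <- dndf_build(cfg, c("a", "b"))
  m$params$Wr[[1]][] <- 0
  m$params$br[[1]][] <- 0
  m$params$theta[[1]] <- rbind(c(20, -20), c(-20, 20))  # leaf 1 -> a, leaf 2 -> b
  m$trained <- TRUE
  m$cfg$standardize <- FALSE
  P <- predict(m, matrix(rnorm(10), 5, 2), type = "prob")
  expect_equal(unname(P), matrix(0.5, 5, 2), tolerance = 1e-6)
})

test_that("more trees do not hurt held-out accuracy beyond noise", {
  accs <- sapply(1:5, function(s) {
    blobs <- make_blobs(n = 200, sep = 0.3, seed = 100 + s)
    tr <- c(1:70, 101:170)
    sapply(c(1, 10), function(nt) {
      fit <- dndf(blobs$X[tr, ], blobs$y[tr], embed_dim = 8,
                  hidden_layers = c(16), n_trees = nt, tree_depth = 3,
                  epochs = 25, seed = s)
      mean(predict(fit, blobs$X[-tr, ]) == blobs$y[-tr])
    })
  })
  expect_gte(mean(accs[2, ]) - mean(accs[1, ]), -0.05)
})

test_that("evaluation metrics match a hand-rolled counter", {
  set.seed(8)
  labels <- c("a", "b", "c")
  truth <- sample(labels, 300, TRUE)
  pred <- ifelse(runif(300) < 0.7, truth, sample(labels, 300, TRUE))
  m <- classification_metrics(truth, pred, labels)
  # brute-force recount
  for (i in seq_along(labels)) for (j in seq_along(labels))
    expect_equal(m$confusion[i, j],
                 sum(truth == labels[i] & pred == labels[j]))
  for (cl in labels) {
    tp <- sum(truth == cl & pred == cl)
    expect_equal(m$precision[[cl]], tp / sum(pred == cl), tolerance = 1e-9)
    expect_equal(m$recall[[cl]], tp / sum(truth == cl), tolerance = 1e-9)
    expect_equal(m$f1[[cl]],
                 2 * tp / (sum(pred == cl) + sum(truth == cl)), tolerance = 1e-9)
  }
  expect_equal(m$accuracy, mean(truth == pred), tolerance = 1e-9)

  # degenerate cases
  perf <- classification_metrics(truth, truth, labels)
  expect_equal(unname(diag(perf$confusion_norm)), rep(1, 3))
  expect_equal(perf$accuracy, 1)
  allb <- classification_metrics(rep(c("a", "b"), 50), rep("a", 100), c("a", "b"))
  expect_equal(allb$accuracy, 0.5)
  expect_equal(unname(allb$recall), c(1, 0))
})

test_that("evaluation rejects labels outside the training classes", {
  blobs <- make_blobs(n = 100)
  fit <- dndf(blobs$X, blobs$y, embed_dim = 4, hidden_layers = c(8),
              n_trees = 2, tree_depth = 2, epochs = 5, seed = 3)
  expect_error(dndf_evaluate(fit, blobs$X, rep("zz", 100)), "evaluation error")
  ev <- dndf_evaluate(fit, blobs$X, blobs$y)
  expect_true(is.matrix(ev$confusion))
})

test_that("cross-validation produces one metrics entry per fold", {
  blobs <- make_blobs(n = 120)
  cv <- cross_validate(blobs$X, blobs$y, folds = 10, seed = 2,
                       train_fn = function(X, y)
                         dndf(X, y, embed_dim = 4, hidden_layers = c(8),
                              n_trees = 2, tree_depth = 2, epochs = 10, seed = 3))
  expect_length(cv$fold_metrics, 10)
  expect_gte(cv$accuracy, 0.9)
})
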