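test_that("forward pass produces valid probabilities and handles degenerate weights", {
  g <- random_normalized_graph(12, 1)
  H0 <- matrix(rnorm(12 * 5), 12, 5)
  W <- gcn_init_weights_for_test(5, 7, 2, seed = 1)
  fw <- gcn_forward(W, g$A_hat, H0)
  expect_equal(unname(rowSums(fw$Z)), rep(1, 12), tolerance = 1e-6)
  # zero first-layer weights collapse to the uniform distribution
  W0 <- W; W0[[1]] <- W0[[1]] * 0
  fw0 <- gcn_forward(W0, g$A_hat, H0)
  expect_equal(unname(fw0$Z), matrix(0.5, 12, 2), tolerance = 1e-12)
  # shape errors name the operand
  expect_error(gcn_forward(W, g$A_hat, H0[, 1:3]), "W\\(0\\)")
  expect_error(gcn_forward(W, g$A_hat, H0[1:5, ]), "A_hat")
})

test_that("sparse forward equals the dense matrix-product oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:30, 1)
    g <- random_normalized_graph(n, seed + 50)
    d <- sample(3:6, 1); h <- sample(4:8, 1)
    H0 <- matrix(rnorm(n * d), n, d)
    W <- gcn_init_weights_for_test(d, h, 2, seed = seed)
    fw <- gcn_forward(W, g$A_hat, H0)
    expect_equal(fw$Z, oracle_forward_dense(W, g$A_hat, H0),
                 tolerance = 1e-6, ignore_attr = TRUE)
    # sparse one-hot input route
    I0 <- onehot_features(n)
    Wn <- gcn_init_weights_for_test(n, h, 2, seed = seed + 1)
    expect_equal(gcn_forward(Wn, g$A_hat, I0)$Z,
                 oracle_forward_dense(Wn, g$A_hat, diag(n)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("masked cross-entropy reproduces closed-form values", {
  Z <- rbind(c(1, 0), c(0.5, 0.5), c(0.25, 0.75), c(0.8, 0.2))
  labels <- c(0L, 0L, 1L, NA)
  # perfect prediction: zero loss (after clamping semantics)
  expect_equal(masked_cross_entropy(Z, labels, 1L), 0, tolerance = 1e-9)
  # uniform binary prediction: ln 2
  expect_equal(masked_cross_entropy(Z, labels, 2L), log(2))
  # mean over three masked docs with probs 0.5, 0.25(->0.75 at label 1), 0.8
  Z3 <- rbind(c(0.5, 0.5), c(0.25, 0.75), c(0.8, 0.2))
  lab3 <- c(0L, 0L, 0L)
  expect_equal(masked_cross_entropy(Z3, lab3, 1:3),
               -(log(0.5) + log(0.25) + log(0.8)) / 3, tolerance = 1e-12)
  # zero probability at the true label is clamped, not -Inf
  Zc <- rbind(c(0, 1))
  expect_true(is.finite(masked_cross_entropy(Zc, 0L, 1L)))
  expect_error(masked_cross_entropy(Z, labels, integer(0)), "empty")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(7)
  g <- random_normalized_graph(8, 3)
  H0 <- matrix(rnorm(8 * 4), 8, 4)
  W <- gcn_init_weights_for_test(4, 5, 2, seed = 3)
  labels <- sample(0:1, 8, replace = TRUE)
  mask <- 1:5
  fw <- gcn_forward(W, g$A_hat, H0, training = TRUE, dropout = 0)
  grads <- textgcn:::gcn_backward(W, g$A_hat, fw$cache, labels, mask)
  eps <- 1e-6
  for (l in 1:2) {
    for (k in 1:3) {
      idx <- arrayInd(k * 3, dim(W[[l]]))
      Wp <- W; Wp[[l]][idx] <- Wp[[l]][idx] + eps
      Wm <- W; Wm[[l]][idx] <- Wm[[l]][idx] - eps
      lp <- masked_cross_entropy(gcn_forward(Wp, g$A_hat, H0)$Z, labels, mask)
      lm <- masked_cross_entropy(gcn_forward(Wm, g$A_hat, H0)$Z, labels, mask)
      expect_equal(grads[[l]][idx], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and is reproducible given the seed", {
  corp <- build_vocabulary(generate_corpus(separable_spec(21, n_docs = 80)),
                           tokenizer_config(min_df = 1L))
  corp <- split_corpus(corp, 0.2, seed = 21)
  g <- build_graph(corp)
  H0 <- onehot_features(g$n)
  labels <- corp$documents$label
  tr <- which(corp$documents$split == "train")
  cfg <- train_config(hidden = 32, max_epochs = 40, seed = 5)
  m1 <- gcn_train(g, H0, labels, tr, cfg)
  expect_lt(m1$state$train_loss[2], m1$state$train_loss[1])
  m2 <- gcn_train(g, H0, labels, tr, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$state$Z, m2$state$Z)
  expect_error(gcn_train(g, H0, labels, integer(0), cfg), "no labelled")
})

test_that("early stopping halts within patience of a validation plateau", {
  corp <- build_vocabulary(generate_corpus(separable_spec(22, n_docs = 60)),
                           tokenizer_config(min_df = 1L))
  g <- build_graph(corp)
  H0 <- onehot_features(g$n)
  labels <- corp$documents$label
  cfg <- train_config(hidden = 16, max_epochs = 200, patience = 10, seed = 2)
  m <- gcn_train(g, H0, labels, seq_len(n_docs(corp)), cfg)
  n_run <- length(m$state$train_loss)
  if (m$state$stop_reason == "early_stop") {
    expect_lte(n_run, m$state$best_epoch + 10)
  } else {
    expect_equal(n_run, 200L)
  }
})

test_that("prediction breaks exact ties toward the non-depression class", {
  g <- random_normalized_graph(4, 9)
  g$D <- 4L
  model <- structure(list(weights = list(matrix(0, 3, 5), matrix(0, 5, 2))),
                     class = "textgcn_model")
  H0 <- matrix(rnorm(12), 4, 3)
  # zero weights -> uniform probabilities -> all ties -> class 0
  expect_equal(gcn_predict(model, g, H0), rep(0L, 4))
})

test_that("document predictions are invariant to word-node relabelling", {
  corp <- build_vocabulary(generate_corpus(separable_spec(23, n_docs = 50)),
                           tokenizer_config(min_df = 1L))
  g <- build_graph(corp)
  b <- hash_backend(16, seed = 4)
  H0 <- backend_features(corp, b)
  labels <- corp$documents$label
  tr <- 1:40
  cfg <- train_config(hidden = 16, max_epochs = 30, dropout = 0, seed = 8)
  m <- gcn_train(g, H0, labels, tr, cfg)
  p1 <- gcn_predict(m, g, H0)
  # permute word nodes consistently in A, A_hat and H0
  set.seed(1); wp <- sample(g$M)
  perm <- c(seq_len(g$D), g$D + wp)
  g2 <- g
  g2$A <- g$A[perm, perm]
  g2 <- normalize_adjacency(g2)
  H0p <- H0[perm, ]
  m2 <- gcn_train(g2, H0p, labels, tr, cfg)
  expect_equal(gcn_predict(m2, g2, H0p), p1)
})

test_that("hyperparameter search returns the best trial over the grid", {
  corp <- build_vocabulary(generate_corpus(separable_spec(24, n_docs = 60)),
                           tokenizer_config(min_df = 1L))
  g <- build_graph(corp)
  H0 <- onehot_features(g$n)
  labels <- corp$documents$label
  space <- list(layers = 2L, hidden = c(8L, 16L), dropout = 0.5,
                lr = 0.02, weight_decay = 0)
  res <- hyperparameter_search(g, H0, labels, seq_len(60),
                               space = space, seed = 3,
                               base_config = train_config(max_epochs = 20))
  expect_equal(nrow(res$trials), 2L)
  expect_equal(res$best_value, max(res$trials$value))
  expect_equal(res$best_config$hidden,
               res$trials$hidden[which.max(res$trials$value)])
  # budget 1 returns the single evaluated config
  res1 <- hyperparameter_search(g, H0, labels, seq_len(60), space = space,
                                strategy = "random", budget = 1, seed = 3,
                                base_config = train_config(max_epochs = 20))
  expect_equal(nrow(res1$trials), 1L)
  expect_error(hyperparameter_search(g, H0, labels, 1:60, space = list()),
               "empty")
  # the default grid enumerates 1200 configurations
  expect_equal(prod(lengths(default_search_space())), 1200)
})

test_that("layer counts beyond two stack propagation layers correctly", {
  g <- random_normalized_graph(10, 12)
  H0 <- matrix(rnorm(40), 10, 4)
  W <- gcn_init_weights_for_test(4, 6, 2, seed = 2, layers = 3)
  fw <- gcn_forward(W, g$A_hat, H0)
  expect_equal(fw$Z, oracle_forward_dense(W, g$A_hat, H0),
               tolerance = 1e-6, ignore_attr = TRUE)
})
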