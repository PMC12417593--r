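#' Training configuration for the graph convolutional classifier
#'
#' Defaults follow the standard protocol for transductive text-graph
#' classification: learning rate 0.02, at most 200 epochs with early stopping
#' after 10 epochs without validation improvement, hidden dimension 200,
#' dropout 0.5, two propagation layers, Adam optimization.
#'
#' @param lr Adam learning rate.
#' @param max_epochs Maximum training epochs (full-batch).
#' @param patience Early-stopping patience in epochs.
#' @param hidden Hidden layer width.
#' @param dropout Dropout probability applied to layer inputs in train mode.
#' @param layers Number of propagation layers (>= 2; ReLU between layers,
#'   softmax after the last).
#' @param weight_decay L2 penalty coefficient added to the gradient.
#' @param val_fraction Fraction of training documents held out (stratified)
#'   as the early-stopping validation set.
#' @param seed Seed controlling weight initialization, dropout masks and the
#'   validation split.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.02, max_epochs = 200L, patience = 10L,
                         hidden = 200L, dropout = 0.5, layers = 2L,
                         weight_decay = 0, val_fraction = 0.1, seed = 1L) {
  stopifnot(lr > 0, max_epochs >= 1, patience >= 1, hidden >= 1,
            dropout >= 0, dropout < 1, layers >= 2, weight_decay >= 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(lr = lr, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), hidden = as.integer(hidden),
                 dropout = dropout, layers = as.integer(layers),
                 weight_decay = weight_decay, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Glorot (uniform) initialization for the stack of weight matrices.
gcn_init_weights <- function(d_in, hidden, n_classes, layers) {
  dims <- c(d_in, rep(hidden, layers - 1L), n_classes)
  lapply(seq_len(layers), function(l) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1L]))
    matrix(stats::runif(dims[l] * dims[l + 1L], -lim, lim), dims[l], dims[l + 1L])
  })
}

# Inverted dropout; sparse inputs are masked on their stored entries.
.dropout <- function(X, p) {
  if (p <= 0) return(list(X = X, mask = NULL))
  if (is(X, "sparseMatrix")) {
    X <- as(X, "CsparseMatrix")
    keep <- stats::rbinom(length(X@x), 1L, 1 - p) / (1 - p)
    X@x <- X@x * keep
    list(X = X, mask = NULL)
  } else {
    mask <- matrix(stats::rbinom(length(X), 1L, 1 - p) / (1 - p), nrow(X), ncol(X))
    list(X = X * mask, mask = mask)
  }
}

.row_softmax <- function(S) {
  S <- as.matrix(S)
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Forward pass of the graph convolutional classifier
#'
#' Each layer propagates `H(l+1) = sigma(A_hat H(l) W(l))` with ReLU between
#' layers; the final layer output is routed through a row softmax to give
#' class probabilities `Z`. In train mode, dropout is applied to every
#' layer's input; eval mode is deterministic.
#'
#' @param weights List of weight matrices (`d x h`, ..., `h x F`).
#' @param A_hat Normalized adjacency (`n x n`, from [normalize_adjacency()]).
#' @param H0 Initial node feature matrix (`n x d`, dense or sparse).
#' @param dropout Dropout probability (ignored unless `training`).
#' @param training Apply dropout and retain intermediates for the backward
#'   pass.
#' @return `list(Z, cache)`; `Z` is the `n x F` probability matrix (rows sum
#'   to 1), `cache` holds layer intermediates when `training`.
#' @export
gcn_forward <- function(weights, A_hat, H0, dropout = 0, training = FALSE) {
  if (nrow(H0) != nrow(A_hat)) {
    stopf("H0 has %d rows but A_hat is %d x %d", nrow(H0), nrow(A_hat), ncol(A_hat))
  }
  L <- length(weights)
  if (ncol(H0) != nrow(weights[[1L]])) {
    stopf("H0 has %d columns but W(0) expects %d", ncol(H0), nrow(weights[[1L]]))
  }
  X <- vector("list", L); S <- vector("list", L); masks <- vector("list", L)
  cur <- H0
  for (l in seq_len(L)) {
    if (training && dropout > 0) {
      dp <- .dropout(cur, dropout)
      cur <- dp$X; masks[[l]] <- dp$mask
    }
    X[[l]] <- cur
    S[[l]] <- as.matrix(A_hat %*% (cur %*% weights[[l]]))
    cur <- if (l < L) pmax(S[[l]], 0) else .row_softmax(S[[l]])
  }
  list(Z = cur,
       cache = if (training) list(X = X, S = S, masks = masks) else NULL)
}

#' Masked cross-entropy loss over labelled document nodes
#'
#' `-mean over masked documents of ln Z[d, label(d)]` (mean reduction keeps
#' the gradient scale independent of the labelled-set size). Probabilities
#' are clamped at `1e-12` before the log.
#'
#' @param Z Probability matrix (`n x F`, document rows first).
#' @param labels Integer labels in `{0,1}` per document (length `D`).
#' @param mask Integer indices of the documents contributing to the loss.
#' @return Scalar loss.
#' @export
masked_cross_entropy <- function(Z, labels, mask) {
  if (length(mask) == 0) stopf("empty loss mask")
  p <- Z[cbind(mask, labels[mask] + 1L)]
  p <- pmax(p, 1e-12)
  -mean(log(p))
}

# Gradients of the masked mean cross-entropy wrt every weight matrix.
gcn_backward <- function(weights, A_hat, cache, labels, mask) {
  L <- length(weights)
  n <- nrow(cache$S[[L]]); Fc <- ncol(cache$S[[L]])
  Z <- .row_softmax(cache$S[[L]])
  dS <- Z
  dS[cbind(mask, labels[mask] + 1L)] <-
    dS[cbind(mask, labels[mask] + 1L)] - 1
  sel <- rep(0, n); sel[mask] <- 1 / length(mask)
  dS <- dS * sel
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    AdS <- as.matrix(A_hat %*% dS)          # A_hat is symmetric
    grads[[l]] <- as.matrix(Matrix::crossprod(cache$X[[l]], AdS))
    if (l > 1L) {
      dX <- AdS %*% t(weights[[l]])
      if (!is.null(cache$masks[[l]])) dX <- dX * cache$masks[[l]]
      dS <- dX * (cache$S[[l - 1L]] > 0)
    }
  }
  grads
}

#' Train the graph convolutional classifier
#'
#' Full-batch Adam on the masked cross-entropy over the labelled training
#' documents. A stratified fraction of the training documents is held out as
#' a validation set; training stops when the validation loss has not
#' improved for `patience` consecutive epochs (or at `max_epochs`) and the
#' parameters from the best validation epoch are returned. Test documents
#' participate in propagation as unlabelled nodes (transductive setting) but
#' never in the loss.
#'
#' @param graph A normalized `textgcn_graph`.
#' @param H0 Initial node feature matrix.
#' @param labels Integer vector of length `D` (`NA` allowed outside
#'   `train_idx`).
#' @param train_idx Indices (into `1..D`) of training documents.
#' @param config A [train_config()].
#' @return A `textgcn_model`: weights, config, and a `state` list with the
#'   probability matrix `Z` (at the best epoch), loss histories, best epoch
#'   and stop reason. Bit-reproducible given the config seed.
#' @export
gcn_train <- function(graph, H0, labels, train_idx, config = train_config()) {
  if (is.null(graph$A_hat)) stopf("graph is not normalized")
  train_idx <- as.integer(train_idx)
  if (length(train_idx) == 0) stopf("no labelled training documents")
  if (any(is.na(labels[train_idx]))) stopf("unlabelled document in train_idx")
  A_hat <- graph$A_hat
  local_seed(config$seed, {
    n_val <- floor(config$val_fraction * length(train_idx))
    if (n_val >= 1 && length(train_idx) - n_val >= 1) {
      lab_tr <- labels[train_idx]
      classes <- sort(unique(lab_tr))
      sizes <- vapply(classes, function(cl) sum(lab_tr == cl), integer(1))
      takes <- stratified_counts(sizes, n_val)
      val_idx <- unlist(lapply(seq_along(classes), function(k) {
        pool <- train_idx[lab_tr == classes[k]]
        if (takes[k] > 0) sample(pool, takes[k]) else integer(0)
      }), use.names = FALSE)
      fit_idx <- setdiff(train_idx, val_idx)
    } else {
      val_idx <- integer(0)
      fit_idx <- train_idx
    }
    W <- gcn_init_weights(ncol(H0), config$hidden, 2L, config$layers)
    mW <- lapply(W, function(w) w * 0); vW <- mW
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    best <- Inf; best_W <- W; best_epoch <- 0L; wait <- 0L
    tr_hist <- numeric(0); val_hist <- numeric(0)
    stop_reason <- "max_epochs"
    for (epoch in seq_len(config$max_epochs)) {
      fw <- gcn_forward(W, A_hat, H0, dropout = config$dropout, training = TRUE)
      tr_loss <- masked_cross_entropy(fw$Z, labels, fit_idx)
      if (!is.finite(tr_loss)) stopf("divergent loss at epoch %d", epoch)
      grads <- gcn_backward(W, A_hat, fw$cache, labels, fit_idx)
      for (l in seq_along(W)) {
        g <- grads[[l]] + config$weight_decay * W[[l]]
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g^2
        mh <- mW[[l]] / (1 - b1^epoch)
        vh <- vW[[l]] / (1 - b2^epoch)
        W[[l]] <- W[[l]] - config$lr * mh / (sqrt(vh) + eps)
      }
      ev <- gcn_forward(W, A_hat, H0, training = FALSE)
      monitor_idx <- if (length(val_idx)) val_idx else fit_idx
      mon <- masked_cross_entropy(ev$Z, labels, monitor_idx)
      tr_hist <- c(tr_hist, tr_loss)
      val_hist <- c(val_hist, mon)
      if (mon < best) {
        best <- mon; best_W <- W; best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) { stop_reason <- "early_stop"; break }
      }
    }
    Zfinal <- gcn_forward(best_W, A_hat, H0, training = FALSE)$Z
    structure(list(weights = best_W, config = config,
                   state = list(Z = Zfinal, train_loss = tr_hist,
                                val_loss = val_hist, best_epoch = best_epoch,
                                best_val_loss = best,
                                stop_reason = stop_reason,
                                val_idx = sort(val_idx))),
              class = "textgcn_model")
  })
}

#' @export
print.textgcn_model <- function(x, ...) {
  dims <- vapply(x$weights, function(w) paste(dim(w), collapse = "x"), character(1))
  cat(sprintf("<textgcn_model> %d layers (%s), best epoch %d (%s)\n",
              length(x$weights), paste(dims, collapse = " -> "),
              x$state$best_epoch, x$state$stop_reason))
  invisible(x)
}

#' Predict document labels
#'
#' Argmax over the class probabilities of the document rows; an exact tie is
#' broken toward the lower class index (0, non-depression).
#'
#' @param model A trained `textgcn_model`.
#' @param graph The `textgcn_graph` the model was trained on.
#' @param H0 The feature matrix used in training.
#' @return Integer vector of predicted labels (length `D`).
#' @export
gcn_predict <- function(model, graph, H0) {
  Z <- gcn_forward(model$weights, graph$A_hat, H0, training = FALSE)$Z
  Zd <- Z[seq_len(graph$D), , drop = FALSE]
  as.integer(Zd[, 2L] > Zd[, 1L])
}

#' @rdname gcn_predict
#' @param object,... S3 method arguments.
#' @export
predict.textgcn_model <- function(object, graph, H0, ...) {
  gcn_predict(object, graph, H0)
}

#' Default hyperparameter search grid
#'
#' Layer count 2--5, hidden width 100--500, dropout, learning rate and weight
#' decay grids (1,200 configurations in total).
#'
#' @return Named list of candidate values.
#' @export
default_search_space <- function() {
  list(layers = c(2L, 3L, 4L, 5L),
       hidden = c(100L, 200L, 300L, 400L, 500L),
       dropout = c(0.01, 0.05, 0.1, 0.5),
       lr = c(0.01, 0.02, 0.03, 0.04, 0.05),
       weight_decay = c(0, 0.005, 0.05))
}

#' Hyperparameter search over the configuration grid
#'
#' Evaluates candidate configurations on a stratified validation subset
#' carved from the training documents (the model for each trial is trained on
#' the remainder). Strategy `"exhaustive"` walks the whole grid;
#' `"random"` samples `budget` configurations without replacement.
#'
#' @param graph,H0,labels,train_idx As in [gcn_train()].
#' @param space Named list of candidate values (see
#'   [default_search_space()]).
#' @param objective Validation metric to maximize (`"accuracy"` or `"f1"`).
#' @param budget Number of trials for the random strategy (`NULL` =
#'   exhaustive).
#' @param strategy `"exhaustive"` or `"random"`.
#' @param seed Seed for the validation carve-out and random sampling.
#' @param base_config [train_config()] supplying the non-searched fields.
#' @param val_fraction Fraction of `train_idx` carved out for trial scoring.
#' @return `list(best_config, best_value, trials)` with a full per-trial log.
#' @export
hyperparameter_search <- function(graph, H0, labels, train_idx,
                                  space = default_search_space(),
                                  objective = c("accuracy", "f1"),
                                  budget = NULL,
                                  strategy = c("exhaustive", "random"),
                                  seed = 1L, base_config = train_config(),
                                  val_fraction = 0.2) {
  objective <- match.arg(objective)
  strategy <- match.arg(strategy)
  if (length(space) == 0 || any(lengths(space) == 0)) stopf("empty search space")
  grid <- do.call(expand.grid, c(space, list(KEEP.OUT.ATTRS = FALSE)))
  rows <- local_seed(seed, {
    if (strategy == "random") {
      if (is.null(budget)) stopf("random strategy requires a budget")
      sample(nrow(grid), min(budget, nrow(grid)))
    } else if (!is.null(budget)) {
      seq_len(min(budget, nrow(grid)))
    } else seq_len(nrow(grid))
  })
  # fixed validation carve-out shared by every trial
  lab_tr <- labels[train_idx]
  classes <- sort(unique(lab_tr))
  sizes <- vapply(classes, function(cl) sum(lab_tr == cl), integer(1))
  takes <- stratified_counts(sizes, max(1L, floor(val_fraction * length(train_idx))))
  val_idx <- local_seed(seed + 1L, unlist(lapply(seq_along(classes), function(k) {
    pool <- train_idx[lab_tr == classes[k]]
    if (takes[k] > 0) sample(pool, takes[k]) else integer(0)
  }), use.names = FALSE))
  fit_idx <- setdiff(train_idx, val_idx)
  score_one <- function(row) {
    cfg <- train_config(lr = grid$lr[row], max_epochs = base_config$max_epochs,
                        patience = base_config$patience,
                        hidden = grid$hidden[row], dropout = grid$dropout[row],
                        layers = grid$layers[row],
                        weight_decay = grid$weight_decay[row],
                        val_fraction = base_config$val_fraction,
                        seed = base_config$seed)
    model <- gcn_train(graph, H0, labels, fit_idx, cfg)
    pred <- gcn_predict(model, graph, H0)
    mt <- evaluate_predictions(labels[val_idx], pred[val_idx])
    mt[[objective]]
  }
  values <- vapply(rows, score_one, numeric(1))
  trials <- cbind(grid[rows, , drop = FALSE], value = values)
  rownames(trials) <- NULL
  best_row <- rows[which.max(values)]
  best_config <- train_config(lr = grid$lr[best_row],
                              max_epochs = base_config$max_epochs,
                              patience = base_config$patience,
                              hidden = grid$hidden[best_row],
                              dropout = grid$dropout[best_row],
                              layers = grid$layers[best_row],
                              weight_decay = grid$weight_decay[best_row],
                              val_fraction = base_config$val_fraction,
                              seed = base_config$seed)
  list(best_config = best_config, best_value = max(values), trials = trials)
}

#' Save / load a model checkpoint as portable text
#'
#' Weights are written as TSV matrices plus a JSON config; the training log
#' as CSV (`epoch`, `train_loss`, `val_loss`).
#'
#' @param model A `textgcn_model`.
#' @param dir Checkpoint directory.
#' @return The directory, invisibly.
#' @export
write_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in seq_along(model$weights)) {
    write.table(model$weights[[l]], file.path(dir, sprintf("W%d.tsv", l - 1L)),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- data.frame(epoch = seq_along(model$state$train_loss),
                    train_loss = model$state$train_loss,
                    val_loss = model$state$val_loss)
  write.table(log, file.path(dir, "training_log.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
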