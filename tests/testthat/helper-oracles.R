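# Independent brute-force oracles. These deliberately share no code with the
# package: dense triple-loop computations over explicitly enumerated windows
# and token sets.

# All sliding windows (as token-id vectors) of the corpus; a non-empty
# document shorter than the window yields itself as one window.
oracle_windows <- function(token_ids, window) {
  wins <- list()
  for (tk in token_ids) {
    n <- length(tk)
    if (n == 0) next
    if (n <= window) {
      wins[[length(wins) + 1L]] <- tk
    } else {
      for (s in 1:(n - window + 1L)) {
        wins[[length(wins) + 1L]] <- tk[s:(s + window - 1L)]
      }
    }
  }
  wins
}

oracle_pmi_dense <- function(token_ids, M, window) {
  wins <- oracle_windows(token_ids, window)
  W <- length(wins)
  cnt <- numeric(M)
  pair <- matrix(0, M, M)
  for (w in wins) {
    u <- unique(w)
    for (a in u) cnt[a] <- cnt[a] + 1
    for (a in u) for (b in u) if (a < b) pair[a, b] <- pair[a, b] + 1
  }
  P <- matrix(0, M, M)
  if (W > 0) {
    for (i in seq_len(M)) for (j in seq_len(M)) {
      if (i < j && pair[i, j] > 0) {
        v <- log((pair[i, j] * W) / (cnt[i] * cnt[j]))
        if (v > 0) { P[i, j] <- v; P[j, i] <- v }
      }
    }
  }
  list(P = P, W = W, word_windows = cnt, pair_windows = pair)
}

oracle_tfidf_dense <- function(token_ids, M) {
  D <- length(token_ids)
  TFIDF <- matrix(0, M, D)
  df <- numeric(M)
  for (d in seq_len(D)) for (w in unique(token_ids[[d]])) df[w] <- df[w] + 1
  for (d in seq_len(D)) {
    for (w in seq_len(M)) {
      tf <- sum(token_ids[[d]] == w)
      if (tf > 0 && df[w] < D) TFIDF[w, d] <- tf * log(D / df[w])
    }
  }
  TFIDF
}

oracle_jaccard_dense <- function(token_ids, threshold = 0) {
  D <- length(token_ids)
  J <- matrix(0, D, D)
  for (i in seq_len(D)) for (j in seq_len(D)) {
    if (i < j) {
      si <- unique(token_ids[[i]]); sj <- unique(token_ids[[j]])
      un <- length(union(si, sj))
      v <- if (un == 0) 0 else length(intersect(si, sj)) / un
      if (v > threshold) { J[i, j] <- v; J[j, i] <- v }
    }
  }
  J
}

# Full dense adjacency in docs-then-words node order.
oracle_adjacency_dense <- function(token_ids, M, window, threshold = 0) {
  D <- length(token_ids)
  n <- D + M
  A <- matrix(0, n, n)
  A[1:D, 1:D] <- oracle_jaccard_dense(token_ids, threshold)
  A[(D + 1):n, (D + 1):n] <- oracle_pmi_dense(token_ids, M, window)$P
  TF <- oracle_tfidf_dense(token_ids, M)
  A[(D + 1):n, 1:D] <- TF
  A[1:D, (D + 1):n] <- t(TF)
  A
}

oracle_normalize_dense <- function(A) {
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  diag(1 / sqrt(d)) %*% At %*% diag(1 / sqrt(d))
}

# Dense straight-line forward pass: plain matrix products, ReLU between
# layers, row softmax at the end.
oracle_forward_dense <- function(weights, A_hat, H0) {
  H <- as.matrix(H0)
  Ad <- as.matrix(A_hat)
  L <- length(weights)
  for (l in seq_len(L)) {
    S <- Ad %*% H %*% weights[[l]]
    if (l < L) {
      H <- S * (S > 0)
    } else {
      E <- exp(S - apply(S, 1, max))
      H <- E / rowSums(E)
    }
  }
  H
}

oracle_confusion <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0L
  for (k in seq_along(y_true)) {
    if (y_true[k] == 1 && y_pred[k] == 1) tp <- tp + 1L
    if (y_true[k] == 0 && y_pred[k] == 0) tn <- tn + 1L
    if (y_true[k] == 0 && y_pred[k] == 1) fp <- fp + 1L
    if (y_true[k] == 1 && y_pred[k] == 0) fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}
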