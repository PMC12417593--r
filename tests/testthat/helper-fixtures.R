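# Programmatic fixtures shared across test files.

# A tokenized corpus straight from whitespace-joined token strings.
toy_corpus <- function(texts, labels = NULL, min_df = 1L) {
  build_vocabulary(corpus_from_texts(texts, labels),
                   tokenizer_config(min_df = min_df))
}

# Random small corpora for oracle-equivalence property tests.
random_toy_corpus <- function(seed, max_docs = 10L, alphabet = 12L,
                              max_len = 12L) {
  set.seed(seed)
  n_docs <- sample(2:max_docs, 1)
  words <- sprintf("t%02d", seq_len(alphabet))
  texts <- vapply(seq_len(n_docs), function(d) {
    paste(sample(words, sample(1:max_len, 1), replace = TRUE), collapse = " ")
  }, character(1))
  toy_corpus(texts)
}

# Token-id lists of a tokenized corpus, for feeding the oracles.
corpus_token_ids <- function(corpus) {
  lapply(corpus$tokens, function(tk) unname(corpus$vocabulary[tk]))
}

# Random normalized graph over n nodes (no corpus semantics), for spectrum
# and forward-pass checks.
random_normalized_graph <- function(n, seed, density = 0.2) {
  set.seed(seed)
  n_edges <- max(1L, round(density * n * (n - 1) / 2))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  take <- pairs[sample(nrow(pairs), min(n_edges, nrow(pairs))), , drop = FALSE]
  w <- runif(nrow(take), 0.1, 2)
  A <- Matrix::sparseMatrix(i = c(take[, 1], take[, 2]),
                            j = c(take[, 2], take[, 1]),
                            x = c(w, w), dims = c(n, n))
  g <- structure(list(n = n, D = n, M = 0L, A = A, A_hat = NULL,
                      node_names = NULL,
                      edge_counts = c(word_word = 0L, word_doc = 0L,
                                      doc_doc = nrow(take))),
                 class = "textgcn_graph")
  normalize_adjacency(g)
}

# Seeded Glorot weights via the package's internal initializer.
gcn_init_weights_for_test <- function(d, h, n_classes, seed, layers = 2L) {
  set.seed(seed)
  textgcn:::gcn_init_weights(d, h, n_classes, layers)
}

# Empty edge sets of each kind, for assembly tests.
new_edges_for_test <- function() {
  mk <- function(kind) {
    structure(data.frame(i = integer(0), j = integer(0), weight = numeric(0)),
              kind = kind, class = c("textgcn_edges", "data.frame"))
  }
  list(ww = mk("word_word"), wd = mk("word_doc"), dd = mk("doc_doc"))
}

# Small separable synthetic spec used by several training tests.
separable_spec <- function(seed, n_docs = 200L, signal = 0.9) {
  synthetic_spec(n_docs = n_docs, class_balance = 0.5, vocab_shared = 120L,
                 vocab_class = 25L, signal_strength = signal,
                 length_mean = 30, length_sd = 8, length_min = 8L,
                 length_max = 60L, emoji_rate = 0.02, seed = seed)
}
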