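#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t tcrossprod drop0 forceSymmetric
NULL

new_edges <- function(i, j, weight, kind) {
  structure(data.frame(i = as.integer(i), j = as.integer(j),
                       weight = as.numeric(weight)),
            kind = kind, class = c("textgcn_edges", "data.frame"))
}

#' @export
print.textgcn_edges <- function(x, ...) {
  cat(sprintf("<textgcn_edges:%s> %d edges\n", attr(x, "kind"), nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# Document token lists as vocabulary indices.
.token_ids <- function(corpus) {
  vocab <- corpus$vocabulary
  lapply(corpus$tokens, function(tk) unname(vocab[tk]))
}

#' Word--word edges from sliding-window pointwise mutual information
#'
#' Enumerates sliding windows of length `window_size` (stride 1) over every
#' document; a non-empty document shorter than the window contributes a
#' single window, a document with no retained tokens contributes none. With
#' `W` total windows, `W(i)` windows containing word `i` and `W(i,j)` windows
#' containing both, `PMI(i,j) = ln[(W(i,j)/W) / ((W(i)/W) (W(j)/W))]`
#' (natural log). Only pairs with `W(i,j) > 0` and strictly positive PMI
#' become edges.
#'
#' @param corpus A tokenized `textgcn_corpus`.
#' @param window_size Window length in tokens (default 20, the customary
#'   co-occurrence window for word--document graph classifiers).
#' @return A `textgcn_edges` set of kind `word_word`, canonical `i < j`,
#'   indices in `1..M`.
#' @export
compute_pmi <- function(corpus, window_size = 20L) {
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L) stopf("window_size must be >= 1")
  ids <- .token_ids(corpus)
  M <- vocab_size(corpus)
  W <- 0
  word_win <- numeric(M)
  pair_chunks <- list()
  for (d in seq_along(ids)) {
    tk <- ids[[d]]
    n <- length(tk)
    if (n == 0) next
    n_win <- max(1L, n - window_size + 1L)
    W <- W + n_win
    win_i <- integer(0); win_j <- integer(0); win_id <- integer(0)
    for (s in seq_len(n_win)) {
      u <- unique(tk[s:min(n, s + window_size - 1L)])
      word_win[u] <- word_win[u] + 1
      if (length(u) >= 2) {
        cmb <- utils::combn(sort(u), 2L)
        win_i <- c(win_i, cmb[1L, ]); win_j <- c(win_j, cmb[2L, ])
      }
    }
    if (length(win_i)) {
      dt <- data.table::data.table(i = win_i, j = win_j)
      pair_chunks[[length(pair_chunks) + 1L]] <- dt[, list(n = .N), by = c("i", "j")]
    }
  }
  if (length(pair_chunks) == 0 || W == 0) {
    return(new_edges(integer(0), integer(0), numeric(0), "word_word"))
  }
  pairs <- data.table::rbindlist(pair_chunks)
  pairs <- pairs[, list(n = sum(n)), by = c("i", "j")]
  pmi <- log((pairs$n * W) / (word_win[pairs$i] * word_win[pairs$j]))
  keep <- pmi > 0
  new_edges(pairs$i[keep], pairs$j[keep], pmi[keep], "word_word")
}

# Sparse document-term count matrix (D x M).
doc_term_matrix <- function(corpus, binary = FALSE) {
  ids <- .token_ids(corpus)
  D <- n_docs(corpus); M <- vocab_size(corpus)
  di <- rep.int(seq_along(ids), lengths(ids))
  wi <- unlist(ids, use.names = FALSE)
  if (length(wi) == 0) return(sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(D, M)))
  m <- sparseMatrix(i = di, j = wi, x = rep(1, length(wi)), dims = c(D, M))
  if (binary) m@x <- rep(1, length(m@x))
  m
}

#' Word--document edges from TF-IDF
#'
#' `weight(w, d) = tf(w, d) * ln(D / df(w))` with raw term counts and an
#' unsmoothed inverse document frequency; a word present in every document
#' has idf 0 and produces no edges.
#'
#' @param corpus A tokenized `textgcn_corpus`.
#' @param smooth_idf Use `ln(1 + D/df)` instead (off by default).
#' @return A `textgcn_edges` set of kind `word_doc` with `i` the word index
#'   (`1..M`) and `j` the document index (`1..D`).
#' @export
compute_tfidf <- function(corpus, smooth_idf = FALSE) {
  D <- n_docs(corpus)
  dtm <- doc_term_matrix(corpus)
  tm <- as(drop0(dtm), "TsparseMatrix")
  if (length(tm@x) == 0) return(new_edges(integer(0), integer(0), numeric(0), "word_doc"))
  dfv <- colSums(dtm > 0)
  idf <- if (smooth_idf) log(1 + D / dfv) else log(D / dfv)
  w <- tm@x * idf[tm@j + 1L]
  keep <- w != 0
  new_edges(tm@j[keep] + 1L, tm@i[keep] + 1L, w[keep], "word_doc")
}

#' Document--document edges from Jaccard similarity of token sets
#'
#' For documents `i != j` with retained-token sets `S_i`, `S_j`,
#' `J = |S_i intersect S_j| / |S_i union S_j|`; an edge is emitted iff
#' `J > threshold`. Two empty token sets have `J = 0` by convention.
#'
#' @param corpus A tokenized `textgcn_corpus`.
#' @param threshold Keep pairs with similarity strictly above this value
#'   (default 0, i.e. every overlapping pair).
#' @return A `textgcn_edges` set of kind `doc_doc`, canonical `i < j`.
#' @export
compute_jaccard <- function(corpus, threshold = 0) {
  if (threshold < 0) stopf("threshold must be >= 0")
  B <- doc_term_matrix(corpus, binary = TRUE)
  sizes <- rowSums(B)
  inter <- as(drop0(tcrossprod(B)), "TsparseMatrix")
  ii <- inter@i + 1L; jj <- inter@j + 1L
  up <- ii < jj
  ii <- ii[up]; jj <- jj[up]; ov <- inter@x[up]
  un <- sizes[ii] + sizes[jj] - ov
  jac <- ifelse(un > 0, ov / un, 0)
  keep <- jac > threshold
  new_edges(ii[keep], jj[keep], jac[keep], "doc_doc")
}

#' Assemble the heterogeneous word--document adjacency matrix
#'
#' Nodes are ordered documents-then-words: documents at rows `1..D`, words at
#' rows `D+1..D+M` (so `n = D + M`). The adjacency holds PMI weights between
#' word pairs, TF-IDF weights between words and documents (mirrored), and
#' Jaccard weights between document pairs; the diagonal is zero --
#' self-connections enter only through the `A + I` term of normalization.
#'
#' @param word_word,word_doc,doc_doc `textgcn_edges` sets from
#'   [compute_pmi()], [compute_tfidf()], [compute_jaccard()].
#' @param D,M Document and word counts.
#' @param node_names Optional character vector of length `D + M`.
#' @return A `textgcn_graph` with the raw adjacency `A` (symmetric sparse,
#'   zero diagonal); run [normalize_adjacency()] to fill `A_hat`.
#' @export
assemble_adjacency <- function(word_word, word_doc, doc_doc, D, M,
                               node_names = NULL) {
  D <- as.integer(D); M <- as.integer(M); n <- D + M
  ww <- data.frame(i = D + word_word$i, j = D + word_word$j, w = word_word$weight)
  wd <- data.frame(i = D + word_doc$i, j = word_doc$j, w = word_doc$weight)
  dd <- data.frame(i = doc_doc$i, j = doc_doc$j, w = doc_doc$weight)
  tri <- rbind(ww, wd, dd)
  if (nrow(tri)) {
    key <- paste(pmin(tri$i, tri$j), pmax(tri$i, tri$j))
    if (anyDuplicated(key)) {
      dup <- key[anyDuplicated(key)]
      stopf("conflicting duplicate edge for node pair (%s)", dup[1])
    }
    if (any(tri$i == tri$j)) stopf("self-edge in edge sets")
    if (any(tri$i < 1 | tri$j < 1 | tri$i > n | tri$j > n)) stopf("edge index out of range")
    A <- sparseMatrix(i = c(tri$i, tri$j), j = c(tri$j, tri$i),
                      x = c(tri$w, tri$w), dims = c(n, n))
  } else {
    A <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(n, n))
  }
  structure(list(n = n, D = D, M = M, A = A, A_hat = NULL,
                 node_names = node_names,
                 edge_counts = c(word_word = nrow(word_word),
                                 word_doc = nrow(word_doc),
                                 doc_doc = nrow(doc_doc)),
                 window_size = NA_integer_, jaccard_threshold = NA_real_,
                 fingerprint = sprintf("n=%d;nnz=%d;sum=%.10g", n,
                                       length(A@x), sum(A@x))),
            class = "textgcn_graph")
}

#' Symmetric normalization of the adjacency
#'
#' Computes `A_hat = Dt^(-1/2) (A + I) Dt^(-1/2)` where `Dt` is the degree
#' matrix of `A + I`. Every node carries a self-loop, so degrees are at least
#' one and the spectrum of `A_hat` lies in `[-1, 1]`.
#'
#' @param graph A `textgcn_graph` with `A` assembled.
#' @return The graph with `A_hat` filled (symmetric sparse).
#' @export
normalize_adjacency <- function(graph) {
  A <- graph$A
  if (any(A@x < 0)) stopf("negative edge weight encountered")
  At <- A + Diagonal(graph$n)
  dinv <- 1 / sqrt(rowSums(At))
  Dh <- Diagonal(graph$n, dinv)
  graph$A_hat <- forceSymmetric(Dh %*% At %*% Dh)
  graph
}

#' Build the full text graph from a tokenized corpus
#'
#' Convenience wrapper running [compute_pmi()], [compute_tfidf()],
#' [compute_jaccard()], [assemble_adjacency()] and [normalize_adjacency()].
#'
#' @param corpus A tokenized `textgcn_corpus`.
#' @param window_size PMI sliding-window length.
#' @param jaccard_threshold Minimum Jaccard similarity for document edges.
#' @param smooth_idf Passed to [compute_tfidf()].
#' @return A normalized `textgcn_graph`.
#' @export
build_graph <- function(corpus, window_size = 20L, jaccard_threshold = 0,
                        smooth_idf = FALSE) {
  if (is.null(corpus$vocabulary)) stopf("corpus must be tokenized (build_vocabulary)")
  g <- assemble_adjacency(compute_pmi(corpus, window_size),
                          compute_tfidf(corpus, smooth_idf),
                          compute_jaccard(corpus, jaccard_threshold),
                          D = n_docs(corpus), M = vocab_size(corpus),
                          node_names = c(corpus$documents$doc_id,
                                         names(corpus$vocabulary)))
  g$window_size <- as.integer(window_size)
  g$jaccard_threshold <- jaccard_threshold
  normalize_adjacency(g)
}

#' @export
print.textgcn_graph <- function(x, ...) {
  cat(sprintf("<textgcn_graph> n = %d (D = %d docs + M = %d words), %d stored entries\n",
              x$n, x$D, x$M, length(x$A@x)))
  cat(sprintf("  edges: %d word-word, %d word-doc, %d doc-doc; A_hat %s\n",
              x$edge_counts["word_word"], x$edge_counts["word_doc"],
              x$edge_counts["doc_doc"],
              if (is.null(x$A_hat)) "not computed" else "computed"))
  invisible(x)
}

#' Export graph artifacts
#'
#' `write_graph_mtx` writes `A` (and `A_hat` when present) in Matrix Market
#' format; `write_edge_tsv` writes an edge list (`src`, `dst`, `kind`,
#' `weight`, upper triangle, 1-based node indices); `write_node_map_tsv`
#' writes `index`, `kind` (`doc`/`word`), `name`.
#'
#' @param graph A `textgcn_graph`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_graph_mtx <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(graph$A, "generalMatrix"), file.path(dir, "A.mtx"))
  if (!is.null(graph$A_hat)) {
    Matrix::writeMM(as(graph$A_hat, "generalMatrix"), file.path(dir, "A_hat.mtx"))
  }
  invisible(dir)
}

#' @rdname write_graph_mtx
#' @param path Output TSV path.
#' @export
write_edge_tsv <- function(graph, path) {
  Tm <- as(drop0(graph$A), "TsparseMatrix")
  ii <- Tm@i + 1L; jj <- Tm@j + 1L
  up <- ii < jj
  ii <- ii[up]; jj <- jj[up]; w <- Tm@x[up]
  kind <- ifelse(ii <= graph$D & jj <= graph$D, "doc_doc",
                 ifelse(ii > graph$D & jj > graph$D, "word_word", "word_doc"))
  write.table(data.frame(src = ii, dst = jj, kind = kind, weight = w),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_mtx
#' @export
write_node_map_tsv <- function(graph, path) {
  kind <- c(rep("doc", graph$D), rep("word", graph$M))
  nm <- graph$node_names %||% as.character(seq_len(graph$n))
  write.table(data.frame(index = seq_len(graph$n), kind = kind, name = nm),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
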