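#' One-hot node features
#'
#' The baseline initial feature matrix: the `n x n` identity, stored sparse.
#' Each node's feature is its own indicator, so all information the model can
#' use lives in the graph structure.
#'
#' @param n Node count (`D + M`).
#' @return A sparse identity matrix with attribute `source = "onehot"`.
#' @export
onehot_features <- function(n) {
  if (n < 1) stopf("n must be >= 1")
  H0 <- Diagonal(n, 1)
  attr(H0, "source") <- "onehot"
  H0
}

#' Deterministic hash embedding backend
#'
#' An embedding backend for tests and synthetic experiments: every token maps
#' to a fixed pseudo-random vector in `[-1, 1]^dim` derived from a string
#' hash of the token and the seed (no model weights, no network); the
#' sequence vector is the mean of the token vectors, standing in for a
#' CLS-style summary. In *signal mode* a fixed class-direction vector is
#' added to (subtracted from) tokens in the positive (negative) lexicon,
#' which plants class signal purely in embedding space.
#'
#' @param dim Embedding dimension.
#' @param seed Integer seed; same token + same seed gives the identical
#'   vector across calls and sessions.
#' @param max_len Maximum tokens per encode call (longer documents are
#'   chunked by [embed_document()]).
#' @param signal Optional `list(positive = chr, negative = chr,
#'   strength = numeric)` enabling signal mode.
#' @return A `textgcn_backend`: `list(name, dim, max_len, encode)` where
#'   `encode(tokens)` returns `list(sequence, tokens)` with a `dim` vector
#'   and a `length(tokens) x dim` matrix aligned to the input tokens.
#' @export
hash_backend <- function(dim, seed = 0L, max_len = 512L, signal = NULL) {
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) stopf("dim must be >= 1")
  direction <- NULL
  if (!is.null(signal)) {
    stopifnot(is.character(signal$positive), is.character(signal$negative))
    strength <- signal$strength %||% 1
    u <- lcg_runif_sym(str_hash31("class-direction", seed), dim)$values
    direction <- strength * u / sqrt(sum(u^2))
  }
  cache <- new.env(hash = TRUE, parent = emptyenv())
  token_vec <- function(tok) {
    v <- cache[[tok]]
    if (is.null(v)) {
      v <- lcg_runif_sym(str_hash31(tok, seed), dim)$values
      if (!is.null(direction)) {
        if (tok %in% signal$positive) v <- v + direction
        else if (tok %in% signal$negative) v <- v - direction
      }
      cache[[tok]] <- v
    }
    v
  }
  encode <- function(tokens) {
    if (length(tokens) == 0) {
      return(list(sequence = numeric(dim),
                  tokens = matrix(numeric(0), 0, dim)))
    }
    tv <- do.call(rbind, lapply(tokens, token_vec))
    list(sequence = colMeans(tv), tokens = tv)
  }
  structure(list(name = if (is.null(signal)) "hash" else "hash-signal",
                 dim = dim, max_len = as.integer(max_len), encode = encode),
            class = "textgcn_backend")
}

#' @export
print.textgcn_backend <- function(x, ...) {
  cat(sprintf("<textgcn_backend:%s> dim = %d, max_len = %d\n",
              x$name, x$dim, x$max_len))
  invisible(x)
}

#' Embed one document through a backend, chunking long inputs
#'
#' Documents within the backend's position limit are encoded in one call and
#' the backend's sequence vector (the CLS-style summary) becomes the document
#' vector. Longer documents are split into consecutive chunks of at most
#' `max_len` tokens; the document vector is the elementwise mean of the chunk
#' sequence vectors and per-token vectors are concatenated across chunks, so
#' every token still contributes to word-node pooling. Backends wrapping
#' subword tokenizers must return vectors already aligned to the input tokens
#' (mean-pooling subword pieces per token).
#'
#' @param tokens Character vector of document tokens.
#' @param backend A `textgcn_backend`.
#' @param doc_id Optional id used in error messages.
#' @return `list(doc_vector, token_vectors)` with `token_vectors` a
#'   `length(tokens) x dim` matrix.
#' @export
embed_document <- function(tokens, backend, doc_id = NULL) {
  n <- length(tokens)
  ml <- backend$max_len
  enc_try <- function(chunk) {
    out <- tryCatch(backend$encode(chunk), error = function(e) {
      stopf("backend %s failed%s: %s", backend$name,
            if (is.null(doc_id)) "" else paste0(" on document ", doc_id),
            conditionMessage(e))
    })
    if (length(out$sequence) != backend$dim || ncol(out$tokens) != backend$dim) {
      stopf("backend %s returned dimension != %d", backend$name, backend$dim)
    }
    if (nrow(out$tokens) != length(chunk)) {
      stopf("backend %s returned %d token vectors for %d tokens",
            backend$name, nrow(out$tokens), length(chunk))
    }
    out
  }
  if (n <= ml) {
    out <- enc_try(tokens)
    return(list(doc_vector = out$sequence, token_vectors = out$tokens))
  }
  starts <- seq(1L, n, by = ml)
  chunks <- lapply(starts, function(s) tokens[s:min(n, s + ml - 1L)])
  encs <- lapply(chunks, enc_try)
  seqs <- do.call(rbind, lapply(encs, `[[`, "sequence"))
  list(doc_vector = colMeans(seqs),
       token_vectors = do.call(rbind, lapply(encs, `[[`, "tokens")))
}

#' Pool per-occurrence token vectors into word-node features
#'
#' For each vocabulary word, collects the contextual vector of every
#' occurrence of the word across all documents and reduces the collection
#' elementwise. The default is the minimum, yielding a conservative
#' representation dominated by the word's lowest coordinate values across
#' contexts; mean and max pooling are available alternatives.
#'
#' @param token_vectors_by_doc List (one per document) of
#'   `n_tokens x dim` matrices from [embed_document()].
#' @param corpus The tokenized `textgcn_corpus` the vectors came from.
#' @param pooling One of `"min"`, `"mean"`, `"max"`.
#' @param fallback Vector used for a vocabulary word with no collected
#'   occurrence (`"zero"` or `"none"` to error).
#' @return `M x dim` matrix in vocabulary-index order.
#' @export
word_features_from_backend <- function(token_vectors_by_doc, corpus,
                                       pooling = c("min", "mean", "max"),
                                       fallback = "zero") {
  pooling <- match.arg(pooling)
  pf <- switch(pooling,
               min = function(m) apply(m, 2, min),
               max = function(m) apply(m, 2, max),
               mean = function(m) colMeans(m))
  M <- vocab_size(corpus)
  dim <- ncol(token_vectors_by_doc[[1]])
  ids <- .token_ids(corpus)
  all_ids <- unlist(ids, use.names = FALSE)
  all_vecs <- do.call(rbind, token_vectors_by_doc)
  if (length(all_ids) != nrow(all_vecs)) {
    stopf("token vectors (%d rows) do not align with corpus tokens (%d)",
          nrow(all_vecs), length(all_ids))
  }
  out <- matrix(0, M, dim)
  grp <- split(seq_along(all_ids), all_ids)
  missing <- setdiff(as.character(seq_len(M)), names(grp))
  if (length(missing)) {
    if (identical(fallback, "none")) stopf("no occurrence collected for %d word(s)", length(missing))
    warnf("%d vocabulary word(s) had no collected occurrence; zero fallback used",
          length(missing))
  }
  for (w in names(grp)) {
    out[as.integer(w), ] <- pf(all_vecs[grp[[w]], , drop = FALSE])
  }
  out
}

#' Build the full node feature matrix from an embedding backend
#'
#' Rows `1..D` are document vectors (CLS-style sequence summaries, chunked
#' for long documents) in document order; rows `D+1..D+M` are pooled word
#' vectors in vocabulary-index order.
#'
#' @param corpus A tokenized `textgcn_corpus`.
#' @param backend A `textgcn_backend`.
#' @param pooling Word-occurrence pooling (default `"min"`).
#' @return `(D+M) x dim` dense matrix with attributes `source`
#'   (`"backend:<name>"`) and `pooling`.
#' @export
backend_features <- function(corpus, backend, pooling = "min") {
  if (is.null(corpus$tokens)) stopf("corpus must be tokenized")
  embs <- lapply(seq_len(n_docs(corpus)), function(i) {
    embed_document(corpus$tokens[[i]], backend,
                   doc_id = corpus$documents$doc_id[i])
  })
  doc_mat <- do.call(rbind, lapply(embs, `[[`, "doc_vector"))
  word_mat <- word_features_from_backend(lapply(embs, `[[`, "token_vectors"),
                                         corpus, pooling = pooling)
  H0 <- rbind(doc_mat, word_mat)
  if (any(!is.finite(H0))) stopf("non-finite entry in feature matrix")
  attr(H0, "source") <- paste0("backend:", backend$name)
  attr(H0, "pooling") <- pooling
  H0
}

#' Export a node feature matrix
#'
#' Dense matrices are written as TSV; sparse one-hot features as Matrix
#' Market. A sidecar JSON records source, dimension and pooling.
#'
#' @param H0 Feature matrix from [onehot_features()] or [backend_features()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_features <- function(H0, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is(H0, "sparseMatrix")) {
    Matrix::writeMM(as(as(H0, "CsparseMatrix"), "generalMatrix"),
                    file.path(dir, "H0.mtx"))
  } else {
    write.table(as.matrix(H0), file.path(dir, "H0.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  meta <- list(source = attr(H0, "source") %||% "unknown",
               dim = ncol(H0), n = nrow(H0),
               pooling = attr(H0, "pooling"))
  jsonlite::write_json(meta, file.path(dir, "features.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
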