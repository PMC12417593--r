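#' Run the full detection pipeline on a corpus
#'
#' Tokenizes, builds the heterogeneous graph, constructs node features,
#' splits 80:20 (stratified), trains the graph convolutional classifier
#' transductively and evaluates on the held-out documents. All randomness is
#' derived from `seed`, so a rerun with the same inputs is byte-identical.
#'
#' @param corpus A labelled `textgcn_corpus` (raw text), e.g. from
#'   [generate_corpus()] or [read_corpus()].
#' @param seed Integer master seed.
#' @param features `"onehot"`, or a `textgcn_backend`, or a function
#'   `(corpus, graph) -> H0`.
#' @param tokenizer A [tokenizer_config()].
#' @param window_size,jaccard_threshold Graph parameters.
#' @param test_fraction Held-out fraction for the 80:20 protocol.
#' @param config A [train_config()]; its seed is overridden by `seed`.
#' @param pooling Word-feature pooling when a backend is used.
#' @param out_dir Optional run directory; when given, the corpus, graph,
#'   features, checkpoint and report are written under it.
#' @return A report list: test metrics, confusion counts, training summary
#'   and provenance (seeds, config, graph fingerprint).
#' @export
run_pipeline <- function(corpus, seed = 1L, features = "onehot",
                         tokenizer = tokenizer_config(min_df = 1L),
                         window_size = 20L, jaccard_threshold = 0,
                         test_fraction = 0.2, config = train_config(),
                         pooling = "min", out_dir = NULL) {
  corpus <- build_vocabulary(corpus, tokenizer)
  corpus <- split_corpus(corpus, test_fraction, seed = seed)
  graph <- build_graph(corpus, window_size, jaccard_threshold)
  H0 <- if (is.function(features)) {
    features(corpus, graph)
  } else if (inherits(features, "textgcn_backend")) {
    backend_features(corpus, features, pooling = pooling)
  } else if (identical(features, "onehot")) {
    onehot_features(graph$n)
  } else stopf("unknown feature source")
  labels <- corpus$documents$label
  train_idx <- which(corpus$documents$split == "train")
  test_idx <- which(corpus$documents$split == "test")
  cfg <- config; cfg$seed <- as.integer(seed)
  model <- gcn_train(graph, H0, labels, train_idx, cfg)
  pred <- gcn_predict(model, graph, H0)
  mt <- suppressWarnings(evaluate_predictions(labels[test_idx], pred[test_idx]))
  report <- list(
    metrics = mt[c("accuracy", "precision", "recall", "f1")],
    confusion = mt[c("TP", "TN", "FP", "FN")],
    n_docs = n_docs(corpus), vocab_size = vocab_size(corpus),
    n_train = length(train_idx), n_test = length(test_idx),
    training = list(best_epoch = model$state$best_epoch,
                    epochs_run = length(model$state$train_loss),
                    best_val_loss = model$state$best_val_loss,
                    stop_reason = model$state$stop_reason),
    provenance = list(seed = as.integer(seed),
                      feature_source = attr(H0, "source") %||% "custom",
                      window_size = as.integer(window_size),
                      jaccard_threshold = jaccard_threshold,
                      test_fraction = test_fraction,
                      train_config = unclass(cfg),
                      graph_fingerprint = graph$fingerprint))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_corpus_jsonl(corpus, file.path(out_dir, "corpus.jsonl"))
    write_vocab_tsv(corpus, file.path(out_dir, "vocabulary.tsv"))
    write_graph_mtx(graph, file.path(out_dir, "graph"))
    write_node_map_tsv(graph, file.path(out_dir, "graph", "nodes.tsv"))
    write_checkpoint(model, file.path(out_dir, "model"))
    write_report_json(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Serialize a pipeline report deterministically
#'
#' Fixed key order and full-precision numbers, so identical runs produce
#' byte-identical files.
#'
#' @param report Output of [run_pipeline()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
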