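#' Confusion counts for binary depression detection
#'
#' The positive class is depression (label 1): TP counts depressed documents
#' correctly identified, TN non-depressed correctly identified, FP
#' non-depressed flagged as depressed, FN depressed missed.
#'
#' @param y_true,y_pred Equal-length integer vectors with values in `{0,1}`.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stopf("y_true (%d) and y_pred (%d) differ in length",
          length(y_true), length(y_pred))
  }
  if (any(is.na(y_true)) || any(is.na(y_pred)) ||
      !all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stopf("labels must be 0/1 with no missing values")
  }
  c(TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FP = sum(y_true == 0L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == 0L))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); precision = TP/(TP+FP); recall =
#' TP/(TP+FN); F1 = 2 * precision * recall / (precision + recall). A ratio
#' with zero denominator is reported as 0 with a warning (the convention for
#' degenerate folds on imbalanced data).
#'
#' @param TP,TN,FP,FN Non-negative counts, not all zero.
#' @return Named numeric vector of the four metrics.
#' @export
metrics_from_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0)) stopf("negative confusion count")
  total <- sum(counts)
  if (total == 0) stopf("all confusion counts are zero")
  safe_div <- function(num, den, what) {
    if (den == 0) { warnf("%s undefined (zero denominator); reporting 0", what); 0 }
    else num / den
  }
  accuracy <- (TP + TN) / total
  precision <- safe_div(TP, TP + FP, "precision")
  recall <- safe_div(TP, TP + FN, "recall")
  f1 <- if (precision + recall == 0) {
    warnf("F1 undefined (precision + recall = 0); reporting 0"); 0
  } else 2 * precision * recall / (precision + recall)
  c(accuracy = accuracy, precision = precision, recall = recall, f1 = f1)
}

#' @rdname metrics_from_counts
#' @param y_true,y_pred Label vectors, passed through [confusion_counts()].
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  cc <- confusion_counts(y_true, y_pred)
  out <- c(as.list(metrics_from_counts(cc["TP"], cc["TN"], cc["FP"], cc["FN"])),
           as.list(cc))
  names(out) <- c("accuracy", "precision", "recall", "f1", "TP", "TN", "FP", "FN")
  out
}

#' K-fold cross-validated evaluation of the classifier
#'
#' The graph and feature matrix are built once from the full corpus
#' (transductive protocol: every document is a node throughout); for each
#' fold, that fold's labels are withheld from training, a model is trained
#' fresh on the remaining documents, and the four metrics are recorded on the
#' fold. Every document is tested exactly once.
#'
#' @param corpus A labelled, tokenized `textgcn_corpus`.
#' @param k Number of folds.
#' @param seed Seed for fold assignment and training.
#' @param feature_fun Function `(corpus, graph) -> H0` (e.g. one-hot or a
#'   backend wrapper).
#' @param config A [train_config()] (its seed is combined with the fold
#'   index so folds get distinct but reproducible initializations).
#' @param window_size,jaccard_threshold Graph construction parameters.
#' @param stratify Stratify the fold assignment.
#' @return A `textgcn_report`: per-fold metric table, unweighted means and
#'   standard deviations, fold assignment and provenance.
#' @export
crossvalidate <- function(corpus, k = 5L, seed = 1L,
                          feature_fun = function(corpus, graph) onehot_features(graph$n),
                          config = train_config(),
                          window_size = 20L, jaccard_threshold = 0,
                          stratify = TRUE) {
  corpus <- kfold_assign(corpus, k, seed, stratify = stratify)
  graph <- build_graph(corpus, window_size, jaccard_threshold)
  H0 <- feature_fun(corpus, graph)
  labels <- corpus$documents$label
  folds <- corpus$documents$fold
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    cfg <- config; cfg$seed <- config$seed + f
    model <- gcn_train(graph, H0, labels, train_idx, cfg)
    pred <- gcn_predict(model, graph, H0)
    if (length(unique(labels[test_idx])) < 2) {
      warnf("fold %d contains a single class", f)
    }
    mt <- suppressWarnings(evaluate_predictions(labels[test_idx], pred[test_idx]))
    per_fold[[f]] <- data.frame(fold = f, accuracy = mt$accuracy,
                                precision = mt$precision, recall = mt$recall,
                                f1 = mt$f1, TP = mt$TP, TN = mt$TN,
                                FP = mt$FP, FN = mt$FN)
  }
  per_fold <- do.call(rbind, per_fold)
  metrics <- c("accuracy", "precision", "recall", "f1")
  structure(list(per_fold = per_fold,
                 mean = vapply(metrics, function(m) mean(per_fold[[m]]), numeric(1)),
                 sd = vapply(metrics, function(m) sd(per_fold[[m]]), numeric(1)),
                 k = k, seed = seed, folds = folds,
                 feature_source = attr(H0, "source") %||% "custom",
                 graph_fingerprint = graph$fingerprint,
                 config = unclass(config)),
            class = "textgcn_report")
}

#' @export
print.textgcn_report <- function(x, ...) {
  cat(sprintf("<textgcn_report> %d-fold CV, features: %s\n", x$k, x$feature_source))
  for (m in names(x$mean)) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$mean[m], x$sd[m]))
  }
  invisible(x)
}

#' Paired t-test between two per-fold metric vectors
#'
#' Two-sided paired t-test on the fold-wise differences (the fold is the
#' pairing unit). Degenerate cases follow declared conventions: all
#' differences zero gives `t = 0, p = 1`; zero-variance differences with a
#' nonzero mean give `p = 0` with `t = +/-Inf`, flagged in the result.
#' Significance stars: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param metric_a,metric_b Equal-length per-fold metric vectors from
#'   identical fold partitions.
#' @return `list(t, p, stars, degenerate)`.
#' @export
paired_ttest <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b)) stopf("vectors differ in length")
  if (length(metric_a) < 2) stopf("need at least 2 folds for a paired t-test")
  d <- metric_a - metric_b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      res <- list(t = 0, p = 1, degenerate = FALSE)
    } else {
      res <- list(t = sign(mean(d)) * Inf, p = 0, degenerate = TRUE)
    }
  } else {
    tt <- t.test(metric_a, metric_b, paired = TRUE)
    res <- list(t = unname(tt$statistic), p = unname(tt$p.value),
                degenerate = FALSE)
  }
  res$stars <- if (res$p < 0.001) "***" else if (res$p < 0.01) "**"
               else if (res$p < 0.05) "*" else ""
  res
}

#' Model-comparison table with significance stars
#'
#' Rows are models, columns the four metrics (4-decimal formatting); every
#' non-baseline cell carries the paired-t-test stars of that model's per-fold
#' metric vector against the baseline's. All reports must come from the same
#' fold partition.
#'
#' @param reports Named list of `textgcn_report` objects.
#' @param baseline Name of the baseline report in `reports`.
#' @return A data.frame of formatted cells with attribute `"numeric"`
#'   holding the unformatted means.
#' @export
report_table <- function(reports, baseline) {
  if (!baseline %in% names(reports)) stopf("baseline %s not in reports", dQuote(baseline))
  folds0 <- reports[[baseline]]$folds
  for (nm in names(reports)) {
    if (!identical(reports[[nm]]$folds, folds0)) {
      stopf("report %s uses a different fold partition than the baseline", dQuote(nm))
    }
  }
  metrics <- c("accuracy", "precision", "recall", "f1")
  num <- t(vapply(reports, function(r) r$mean[metrics], numeric(4)))
  cells <- matrix("", nrow = length(reports), ncol = 4,
                  dimnames = list(names(reports), metrics))
  for (nm in names(reports)) {
    for (m in metrics) {
      stars <- ""
      if (nm != baseline) {
        stars <- paired_ttest(reports[[nm]]$per_fold[[m]],
                              reports[[baseline]]$per_fold[[m]])$stars
      }
      cells[nm, m] <- sprintf("%.4f%s", reports[[nm]]$mean[m], stars)
    }
  }
  out <- data.frame(model = names(reports), cells, check.names = FALSE,
                    row.names = NULL)
  attr(out, "numeric") <- num
  out
}

#' Write a comparison table as TSV and Markdown
#'
#' @param table Output of [report_table()].
#' @param path_tsv,path_md Output paths (either may be `NULL`).
#' @return Invisibly, the table.
#' @export
write_report_table <- function(table, path_tsv = NULL, path_md = NULL) {
  if (!is.null(path_tsv)) {
    write.table(table, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_md)) {
    hdr <- paste0("| ", paste(names(table), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(table)), collapse = "|"), "|")
    rows <- apply(table, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(hdr, sep, rows), path_md)
  }
  invisible(table)
}
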