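#' Tokenizer configuration
#'
#' Settings controlling how raw post text is turned into tokens. The guiding
#' principle is that emojis and ASCII emoticons are affect-bearing signal in
#' social-media text, so by default each one is kept as a single token rather
#' than being stripped as punctuation noise.
#'
#' @param lowercase Lowercase alphabetic tokens. Emojis, emoticons and
#'   sentinel tokens are never case-folded (lowercasing `":D"` would corrupt
#'   it).
#' @param min_df Minimum document frequency for a token to enter the
#'   vocabulary. Defaults to 5, the customary corpus-level pruning threshold
#'   for word--document graph classifiers; lower it on small corpora.
#' @param keep_emoji Emit each emoji sequence (including skin-tone and
#'   zero-width-joiner modifiers) as one token.
#' @param keep_emoticons Emit each ASCII emoticon from [emoticon_lexicon()]
#'   as one token.
#' @param stopword_removal Drop common English function words. Off by
#'   default: negations such as "not"/"no" carry affective polarity, and the
#'   built-in list deliberately excludes them.
#' @param url_token Sentinel replacing URLs, or `NULL` to leave URLs to the
#'   word pattern.
#' @param user_token Sentinel replacing `@mentions`, or `NULL`.
#' @param extra Named list of free-form provenance fields carried along with
#'   the config.
#' @return An object of class `tokenizer_config`. Identical config applied to
#'   identical text always yields identical tokens.
#' @examples
#' tokenize("I feel sad :( \U0001F622", tokenizer_config())
#' @export
tokenizer_config <- function(lowercase = TRUE, min_df = 5L,
                             keep_emoji = TRUE, keep_emoticons = TRUE,
                             stopword_removal = FALSE,
                             url_token = "<url>", user_token = "<user>",
                             extra = list()) {
  min_df <- as.integer(min_df)
  if (is.na(min_df) || min_df < 1L) stopf("min_df must be an integer >= 1")
  structure(list(lowercase = isTRUE(lowercase), min_df = min_df,
                 keep_emoji = isTRUE(keep_emoji),
                 keep_emoticons = isTRUE(keep_emoticons),
                 stopword_removal = isTRUE(stopword_removal),
                 url_token = url_token, user_token = user_token,
                 extra = extra),
            class = "tokenizer_config")
}

#' ASCII emoticon lexicon
#'
#' The shipped list of ASCII emoticons recognized by [tokenize()]. Each entry
#' is matched as an indivisible token before the word pattern runs, so none
#' of them can be split into punctuation fragments.
#'
#' @return Character vector of emoticon strings.
#' @export
emoticon_lexicon <- function() {
  c(":-)", ":-(", ":-D", ":-P", ":-p", ":-/", ":-\\", ":-|", ":-O", ":-o",
    ":')", ":'(", ";-)", ";-(",
    ":)", ":(", ":D", ":P", ":p", ":/", ":\\", ":|", ":O", ":o",
    ";)", ";(", "=)", "=(", "=D", "<3", "</3", "xD", "XD", "D:", ":3")
}

# Small English stopword list; negations kept out on purpose.
textgcn_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "if", "then", "of", "at", "by",
    "for", "with", "about", "to", "from", "in", "on", "off", "is", "am",
    "are", "was", "were", "be", "been", "being", "it", "its", "this",
    "that", "these", "those", "as", "so", "than", "too", "very", "i",
    "me", "my", "we", "our", "you", "your", "he", "him", "his", "she",
    "her", "they", "them", "their", "do", "does", "did", "have", "has",
    "had", "will", "would", "can", "could", "s", "t", "just")
}

# Emoji sequence: a base emoji-presentation codepoint (or skin-tone
# modifier) followed by any run of presentation emojis, modifiers,
# variation selector 16 or zero-width joiners, so multi-codepoint
# sequences stay one token.
.emoji_pattern <- paste0(
  "[\\p{Emoji_Presentation}\\x{1F3FB}-\\x{1F3FF}]",
  "[\\p{Emoji_Presentation}\\x{FE0F}\\x{200D}\\x{1F3FB}-\\x{1F3FF}]*")

.word_pattern <- "[\\p{L}\\p{N}_][\\p{L}\\p{N}_']*"

.regex_escape <- function(x) {
  stringi::stri_replace_all_regex(x, "([\\\\^$.|?*+()\\[\\]{}])", "\\\\$1")
}

#' Tokenize raw post text, preserving emojis and emoticons
#'
#' Splits text into word tokens on a Unicode-aware word pattern while
#' emitting every emoji sequence and every recognized ASCII emoticon as
#' exactly one token. URLs and user mentions are replaced by sentinel tokens
#' when the config provides them. Lowercasing applies to word tokens only.
#'
#' @param raw_text A single character string (`NA` is treated as empty).
#' @param config A [tokenizer_config()].
#' @return Character vector of tokens (empty for empty input).
#' @examples
#' tokenize("Sunny feels happy")
#' tokenize("I feel sad :( \U0001F622")
#' @export
tokenize <- function(raw_text, config = tokenizer_config()) {
  if (length(raw_text) != 1L) stopf("tokenize() expects a single string")
  if (is.na(raw_text) || !nzchar(raw_text)) return(character(0))
  x <- raw_text
  if (!is.null(config$url_token)) {
    x <- stringi::stri_replace_all_regex(
      x, "(https?://\\S+|www\\.\\S+)", paste0(" ", config$url_token, " "))
  }
  if (!is.null(config$user_token)) {
    x <- stringi::stri_replace_all_regex(
      x, "(?<!\\w)@\\w+", paste0(" ", config$user_token, " "))
  }
  parts <- character(0)
  if (config$keep_emoticons) {
    emo <- emoticon_lexicon()
    emo <- emo[order(-nchar(emo))]  # longest-first so ":-)" beats ":-"
    parts <- c(parts, paste0("(?:", paste(.regex_escape(emo), collapse = "|"), ")"))
  }
  parts <- c(parts, .emoji_pattern)  # always matched, dropped later if unwanted
  parts <- c(parts, "<url>|<user>", .word_pattern)
  pat <- paste(parts, collapse = "|")
  toks <- stringi::stri_extract_all_regex(x, pat)[[1]]
  if (length(toks) == 1L && is.na(toks[1])) return(character(0))
  is_word <- stringi::stri_detect_regex(toks, paste0("^", .word_pattern, "$"))
  if (!config$keep_emoji) {
    is_emoji <- stringi::stri_detect_regex(toks, paste0("^(?:", .emoji_pattern, ")$"))
    keep <- !(is_emoji & !is_word)
    toks <- toks[keep]; is_word <- is_word[keep]
  }
  if (config$lowercase) toks[is_word] <- stringi::stri_trans_tolower(toks[is_word])
  if (config$stopword_removal) {
    toks <- toks[!(toks %in% textgcn_stopwords())]
  }
  toks
}

new_corpus <- function(documents, tokens = NULL, vocabulary = NULL,
                       df = NULL, config = NULL) {
  structure(list(documents = documents, tokens = tokens,
                 vocabulary = vocabulary, df = df, config = config),
            class = "textgcn_corpus")
}

#' @export
print.textgcn_corpus <- function(x, ...) {
  cat(sprintf("<textgcn_corpus> %d documents", nrow(x$documents)))
  if (!is.null(x$vocabulary)) cat(sprintf(", vocabulary of %d words", length(x$vocabulary)))
  nl <- sum(!is.na(x$documents$label))
  cat(sprintf(", %d labelled\n", nl))
  invisible(x)
}

#' Number of documents / vocabulary size
#'
#' @param corpus A `textgcn_corpus`.
#' @return Integer count.
#' @export
n_docs <- function(corpus) nrow(corpus$documents)

#' @rdname n_docs
#' @export
vocab_size <- function(corpus) {
  if (is.null(corpus$vocabulary)) 0L else length(corpus$vocabulary)
}

.coerce_labels <- function(raw, label_map, where) {
  out <- rep(NA_integer_, length(raw))
  raw_chr <- trimws(as.character(raw))
  present <- !is.na(raw) & nzchar(raw_chr)
  bad <- present & !(raw_chr %in% names(label_map))
  if (any(bad)) {
    stopf("unmappable label value %s at record %d of %s",
          dQuote(raw_chr[which(bad)[1]]), which(bad)[1], where)
  }
  out[present] <- as.integer(label_map[raw_chr[present]])
  if (any(!out[present] %in% c(0L, 1L))) {
    stopf("label mapping must target {0,1}")
  }
  out
}

#' Read a labelled post corpus from CSV/TSV/JSONL
#'
#' One document per record, in file order. Labels are coerced to
#' `{0 = non-depression, 1 = depression}` through an explicit mapping;
#' missing or empty label fields yield a missing label (the transductive
#' setting keeps such documents in the graph as unlabelled nodes).
#'
#' @param path Path to a UTF-8 file. CSV/TSV require a header row.
#' @param format One of `"csv"`, `"tsv"`, `"jsonl"`.
#' @param text_field Name of the text column/field (required in every record).
#' @param label_field Name of the label column/field, or `NULL` for an
#'   unlabelled corpus.
#' @param id_field Optional document-id column; defaults to generated ids.
#' @param label_map Named integer vector mapping raw label strings to 0/1.
#' @return An untokenized `textgcn_corpus`.
#' @export
read_corpus <- function(path, format = c("csv", "tsv", "jsonl"),
                        text_field = "text", label_field = "label",
                        id_field = NULL,
                        label_map = c("0" = 0L, "1" = 1L)) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stopf("empty corpus: %s", path)
    recs <- lapply(lines, jsonlite::fromJSON)
    # an array-valued field (e.g. a stored token list) is joined on spaces
    get_field <- function(r, f) {
      v <- r[[f]]
      if (is.null(v) || (length(v) == 1 && is.na(v))) NA_character_
      else paste(as.character(v), collapse = " ")
    }
    texts <- vapply(recs, get_field, character(1), f = text_field)
    raw_lab <- if (is.null(label_field)) rep(NA_character_, length(recs))
               else vapply(recs, get_field, character(1), f = label_field)
    ids <- if (is.null(id_field)) sprintf("doc%05d", seq_along(recs))
           else vapply(recs, get_field, character(1), f = id_field)
  } else {
    df <- if (format == "csv") read.csv(path, colClasses = "character",
                                        check.names = FALSE, encoding = "UTF-8")
          else read.delim(path, colClasses = "character",
                          check.names = FALSE, encoding = "UTF-8")
    if (nrow(df) == 0) stopf("empty corpus: %s", path)
    if (!text_field %in% names(df)) stopf("text field %s missing", dQuote(text_field))
    texts <- df[[text_field]]
    raw_lab <- if (is.null(label_field) || !label_field %in% names(df))
      rep(NA_character_, nrow(df)) else df[[label_field]]
    ids <- if (is.null(id_field)) sprintf("doc%05d", seq_len(nrow(df)))
           else df[[id_field]]
  }
  if (any(is.na(texts))) {
    stopf("text field %s missing at record %d of %s", dQuote(text_field),
          which(is.na(texts))[1], path)
  }
  if (anyDuplicated(ids)) {
    stopf("duplicate doc_id %s in %s", dQuote(ids[anyDuplicated(ids)]), path)
  }
  labels <- .coerce_labels(raw_lab, label_map, path)
  documents <- data.frame(doc_id = ids, raw_text = texts, label = labels,
                          split = NA_character_, fold = NA_integer_,
                          stringsAsFactors = FALSE)
  new_corpus(documents)
}

#' Construct a corpus directly from vectors
#'
#' Convenience constructor used by the synthetic generator and tests.
#'
#' @param texts Character vector of raw documents.
#' @param labels Optional integer labels in `{0,1}` (NA = unlabelled).
#' @param doc_ids Optional ids (defaults to `doc00001`, ...).
#' @return An untokenized `textgcn_corpus`.
#' @export
corpus_from_texts <- function(texts, labels = NULL, doc_ids = NULL) {
  n <- length(texts)
  if (n == 0) stopf("empty corpus")
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  if (is.null(doc_ids)) doc_ids <- sprintf("doc%05d", seq_len(n))
  if (anyDuplicated(doc_ids)) stopf("duplicate doc_id %s", dQuote(doc_ids[anyDuplicated(doc_ids)]))
  stopifnot(length(labels) == n, all(is.na(labels) | labels %in% c(0L, 1L)))
  new_corpus(data.frame(doc_id = doc_ids, raw_text = texts,
                        label = as.integer(labels), split = NA_character_,
                        fold = NA_integer_, stringsAsFactors = FALSE))
}

#' Tokenize a corpus and attach its vocabulary
#'
#' Tokenizes every document with `config`, keeps words whose document
#' frequency is at least `config$min_df`, and indexes the retained words by
#' order of first occurrence across documents (a deterministic bijection onto
#' `1..M`). Document token lists are filtered to the vocabulary.
#'
#' @param corpus A `textgcn_corpus` with raw text.
#' @param config A [tokenizer_config()].
#' @return The corpus with `tokens`, `vocabulary` (named index vector) and
#'   `df` (document frequencies) attached.
#' @export
build_vocabulary <- function(corpus, config = tokenizer_config()) {
  toks <- lapply(corpus$documents$raw_text, tokenize, config = config)
  all_first <- unlist(lapply(toks, unique), use.names = FALSE)
  if (length(all_first) == 0) stopf("corpus has no tokens at all")
  df_tab <- table(factor(all_first, levels = unique(all_first)))
  keep <- names(df_tab)[as.integer(df_tab) >= config$min_df]
  vocab <- seq_along(keep); names(vocab) <- keep
  df <- as.integer(df_tab[keep]); names(df) <- keep
  filtered <- lapply(toks, function(tk) tk[tk %in% keep])
  emptied <- lengths(filtered) == 0 & lengths(toks) > 0
  if (any(emptied)) {
    warnf("%d document(s) lost all tokens to vocabulary filtering (min_df=%d)",
          sum(emptied), config$min_df)
  }
  corpus$tokens <- filtered
  corpus$vocabulary <- vocab
  corpus$df <- df
  corpus$config <- config
  corpus
}

#' Train/test split with optional label stratification
#'
#' Tags every document with `"train"` or `"test"`. The test set has exactly
#' `ceiling(test_fraction * D)` documents; under stratification the per-class
#' test counts follow the class proportions (largest-remainder rounding).
#' Deterministic given `seed`.
#'
#' @param corpus A fully labelled `textgcn_corpus`.
#' @param test_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratify Stratify by label (default `TRUE`, appropriate for the
#'   imbalanced corpora typical of depression detection).
#' @return The corpus with the `split` column filled.
#' @export
split_corpus <- function(corpus, test_fraction, seed, stratify = TRUE) {
  labels <- corpus$documents$label
  if (any(is.na(labels))) stopf("split_corpus requires all documents labelled")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stopf("test_fraction must lie in (0, 1)")
  }
  D <- length(labels)
  n_test <- as.integer(ceiling(test_fraction * D))
  test_idx <- local_seed(seed, {
    if (stratify) {
      classes <- sort(unique(labels))
      sizes <- vapply(classes, function(cl) sum(labels == cl), integer(1))
      if (any(sizes < 2)) stopf("stratification requires >= 2 documents per class")
      takes <- stratified_counts(sizes, n_test)
      unlist(lapply(seq_along(classes), function(k) {
        pool <- which(labels == classes[k])
        sample(pool, takes[k])
      }), use.names = FALSE)
    } else {
      sample(seq_len(D), n_test)
    }
  })
  corpus$documents$split <- "train"
  corpus$documents$split[test_idx] <- "test"
  corpus
}

#' Assign stratified k-fold indices
#'
#' Partitions the documents into `k` folds whose sizes differ by at most one;
#' under stratification, class proportions are approximately preserved per
#' fold. Deterministic given `seed`.
#'
#' @inheritParams split_corpus
#' @param k Number of folds, `2 <= k <= D`.
#' @return The corpus with the `fold` column filled (values in `1..k`).
#' @export
kfold_assign <- function(corpus, k, seed, stratify = TRUE) {
  labels <- corpus$documents$label
  if (any(is.na(labels))) stopf("kfold_assign requires all documents labelled")
  D <- length(labels)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stopf("k must be an integer >= 2")
  if (k > D) stopf("k = %d exceeds the number of documents (%d)", k, D)
  ord <- local_seed(seed, {
    if (stratify) {
      unlist(lapply(sort(unique(labels)), function(cl) {
        pool <- which(labels == cl)
        if (length(pool) > 1) sample(pool) else pool
      }), use.names = FALSE)
    } else {
      sample(seq_len(D))
    }
  })
  folds <- integer(D)
  folds[ord] <- rep_len(seq_len(k), D)  # cyclic across the class-grouped order
  corpus$documents$fold <- folds
  corpus
}

#' Corpus summary statistics
#'
#' Per-class document counts and token-length statistics (mean, population
#' standard deviation, min, max) over the retained token lists, in the shape
#' of a dataset-statistics table row.
#'
#' @param corpus A tokenized `textgcn_corpus`.
#' @return A one-row data.frame with columns `n_docs`, `n_positive`,
#'   `n_negative`, `n_unlabelled`, `vocab_size`, `length_mean`, `length_sd`,
#'   `length_min`, `length_max`.
#' @export
corpus_stats <- function(corpus) {
  if (is.null(corpus$tokens)) stopf("corpus_stats requires a tokenized corpus")
  if (n_docs(corpus) == 0) stopf("empty corpus")
  len <- lengths(corpus$tokens)
  lab <- corpus$documents$label
  data.frame(n_docs = n_docs(corpus),
             n_positive = sum(lab == 1L, na.rm = TRUE),
             n_negative = sum(lab == 0L, na.rm = TRUE),
             n_unlabelled = sum(is.na(lab)),
             vocab_size = vocab_size(corpus),
             length_mean = mean(len),
             length_sd = sd_pop(len),
             length_min = min(len),
             length_max = max(len))
}

#' Serialize a tokenized corpus to JSONL / its vocabulary to TSV
#'
#' `write_corpus_jsonl` writes one JSON object per document with fields
#' `doc_id`, `tokens`, `label`, `split`, `fold`. `write_vocab_tsv` writes
#' `word`, `index` (1-based), `df` columns.
#'
#' @param corpus A tokenized `textgcn_corpus`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  if (is.null(corpus$tokens)) stopf("corpus is not tokenized")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(n_docs(corpus))) {
    rec <- list(doc_id = corpus$documents$doc_id[i],
                tokens = corpus$tokens[[i]],
                label = corpus$documents$label[i],
                split = corpus$documents$split[i],
                fold = corpus$documents$fold[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
write_vocab_tsv <- function(corpus, path) {
  if (is.null(corpus$vocabulary)) stopf("corpus has no vocabulary")
  tab <- data.frame(word = names(corpus$vocabulary),
                    index = as.integer(corpus$vocabulary),
                    df = as.integer(corpus$df[names(corpus$vocabulary)]))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
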