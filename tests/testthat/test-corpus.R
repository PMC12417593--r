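test_that("tokenizer keeps emojis and emoticons as single tokens", {
  expect_identical(tokenize("I feel sad :( \U0001F622"),
                   c("i", "feel", "sad", ":(", "\U0001F622"))
  expect_identical(tokenize("Sunny feels happy"), c("sunny", "feels", "happy"))
  expect_identical(tokenize(""), character(0))
  # multi-codepoint sequence (emoji + skin tone) stays one token
  expect_identical(tokenize("hi \U0001F62D\U0001F3FB"),
                   c("hi", "\U0001F62D\U0001F3FB"))
  # emoticons are never case-folded
  expect_identical(tokenize("great :D"), c("great", ":D"))
  # flags
  expect_identical(tokenize("sad \U0001F622", tokenizer_config(keep_emoji = FALSE)),
                   "sad")
  expect_false(":(" %in% tokenize("sad :(", tokenizer_config(keep_emoticons = FALSE)))
  expect_identical(tokenize("see http://x.io/a @bob"), c("see", "<url>", "<user>"))
})

test_that("tokenization is deterministic and idempotent on emoji-free token lists", {
  cfg <- tokenizer_config()
  for (txt in c("Not happy at all", "a b c d", "I can't even 123")) {
    t1 <- tokenize(txt, cfg)
    expect_identical(tokenize(paste(t1, collapse = " "), cfg), t1)
    expect_identical(tokenize(txt, cfg), t1)
  }
})

test_that("no emoji or lexicon emoticon in the text is lost by tokenization", {
  txts <- c("a \U0001F600 b :) c", ":( :( \U0001F62D", "x <3 \U0001F389:-D")
  for (txt in txts) {
    toks <- tokenize(txt)
    for (e in c("\U0001F600", "\U0001F62D", "\U0001F389")) {
      n_in <- lengths(regmatches(txt, gregexpr(e, txt, fixed = TRUE)))
      expect_equal(sum(toks == e), n_in)
    }
    for (em in c(":)", ":(", "<3", ":-D")) {
      n_in <- lengths(regmatches(txt, gregexpr(em, txt, fixed = TRUE)))
      expect_equal(sum(toks == em), n_in)
    }
  }
})

test_that("read_corpus maps labels, rejects duplicates and empty files", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("text,label", "feeling low,1", "fine today,0", "no label,"), csv)
  corp <- read_corpus(csv, "csv")
  expect_equal(n_docs(corp), 3L)
  expect_equal(corp$documents$label, c(1L, 0L, NA_integer_))

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("text\tlabel", "one\tdepression", "two\tcontrol"), tsv)
  corp2 <- read_corpus(tsv, "tsv",
                       label_map = c(depression = 1L, control = 0L))
  expect_equal(corp2$documents$label, c(1L, 0L))
  expect_error(read_corpus(tsv, "tsv"), "unmappable label")

  jl <- tempfile(fileext = ".jsonl")
  writeLines(c('{"id":"a","text":"x","label":1}',
               '{"id":"a","text":"y","label":0}'), jl)
  expect_error(read_corpus(jl, "jsonl", id_field = "id"), "duplicate doc_id")

  empty <- tempfile(fileext = ".csv")
  writeLines("text,label", empty)
  expect_error(read_corpus(empty, "csv"), "empty corpus")
})

test_that("vocabulary respects min_df and indexes by first occurrence", {
  corp <- toy_corpus(c("a b", "a c", "a"), min_df = 2L)
  expect_identical(names(corp$vocabulary), "a")
  expect_identical(corp$tokens[[1]], "a")

  corp1 <- toy_corpus(c("a b", "a c", "a"), min_df = 1L)
  expect_identical(names(corp1$vocabulary), c("a", "b", "c"))
  expect_equal(vocab_size(corp1), 3L)
  # bijection onto 1..M, stable across reruns
  expect_identical(sort(unname(corp1$vocabulary)), 1:3)
  corp1b <- toy_corpus(c("a b", "a c", "a"), min_df = 1L)
  expect_identical(corp1$vocabulary, corp1b$vocabulary)

  # emojis are ordinary vocabulary entries under the df threshold
  emo <- toy_corpus(rep("\U0001F622 x", 5), min_df = 5L)
  expect_true("\U0001F622" %in% names(emo$vocabulary))

  expect_warning(toy_corpus(c("a a", "b", "a"), min_df = 2L), "lost all tokens")
})

test_that("train/test split is exact, stratified and deterministic", {
  corp <- toy_corpus(sprintf("w%d x", 1:10), labels = rep(c(1L, 0L), c(6, 4)))
  s1 <- split_corpus(corp, 0.2, seed = 11)
  expect_equal(sum(s1$documents$split == "test"), 2L)
  expect_equal(sum(s1$documents$split == "train"), 8L)
  expect_identical(split_corpus(corp, 0.2, seed = 11)$documents$split,
                   s1$documents$split)
  # stratified allocation: 6 pos / 4 neg at fraction 0.5 -> 3 + 2 in test
  s2 <- split_corpus(corp, 0.5, seed = 3)
  test_lab <- s2$documents$label[s2$documents$split == "test"]
  expect_equal(sum(test_lab == 1L), 3L)
  expect_equal(sum(test_lab == 0L), 2L)
  expect_error(split_corpus(corp, 0, seed = 1), "test_fraction")
  solo <- toy_corpus(c("a", "b", "c"), labels = c(1L, 0L, 0L))
  expect_error(split_corpus(solo, 0.3, seed = 1), "stratification")
})

test_that("k-fold assignment partitions the corpus into near-equal folds", {
  corp <- toy_corpus(sprintf("w%d x", 1:10), labels = rep(c(1L, 0L), 5))
  kc <- kfold_assign(corp, 5, seed = 2)
  folds <- kc$documents$fold
  expect_equal(sort(unique(folds)), 1:5)
  expect_true(all(table(folds) == 2))
  expect_identical(kfold_assign(corp, 5, seed = 2)$documents$fold, folds)
  expect_error(kfold_assign(corp, 1, seed = 1), "k must be")
  expect_error(kfold_assign(corp, 11, seed = 1), "exceeds")
  # sizes differ by at most one for k not dividing D
  k3 <- kfold_assign(corp, 3, seed = 4)$documents$fold
  expect_lte(diff(range(table(k3))), 1)
})

test_that("corpus_stats reports class counts and population length statistics", {
  corp <- toy_corpus(c("a b", "a b c d", "a b c d e f"),
                     labels = c(1L, 1L, 0L))
  st <- corpus_stats(corp)
  expect_equal(st$length_mean, 4)
  expect_equal(st$length_min, 2L)
  expect_equal(st$length_max, 6L)
  expect_equal(st$n_positive, 2L)
  expect_equal(st$n_negative, 1L)
  single <- toy_corpus("a b c")
  expect_equal(corpus_stats(single)$length_sd, 0)
})

test_that("corpus JSONL and vocabulary TSV round-trip the essentials", {
  corp <- toy_corpus(c("a b :)", "a c"), labels = c(1L, 0L))
  p <- tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corp, p)
  lines <- readLines(p)
  expect_length(lines, 2)
  rec <- jsonlite::fromJSON(lines[1])
  expect_identical(rec$tokens, corp$tokens[[1]])
  expect_equal(rec$label, 1L)
  v <- tempfile(fileext = ".tsv")
  write_vocab_tsv(corp, v)
  tab <- read.delim(v)
  expect_identical(tab$word, names(corp$vocabulary))
  expect_identical(tab$index, unname(corp$vocabulary))
})
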