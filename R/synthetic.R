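# Emoji inventories used by the generator: fully-qualified presentation
# emojis only, so the tokenizer's emoji pattern always captures them whole.
.emoji_positive <- c("\U0001F622", "\U0001F62D", "\U0001F494", "\U0001F61E")  # sad set
.emoji_negative <- c("\U0001F600", "\U0001F60A", "\U0001F389", "\U0001F31E")  # upbeat set

#' Specification of a synthetic labelled post corpus
#'
#' Describes a binary-labelled corpus with a shared Zipf-weighted vocabulary,
#' class-specific lexicons, class-conditional emoji injection and a truncated
#' normal length distribution. Generation is fully determined by the seed.
#'
#' @param n_docs Number of documents.
#' @param class_balance Fraction of positive (depression) documents.
#' @param vocab_shared Size of the shared vocabulary.
#' @param vocab_class Size of each class-specific lexicon.
#' @param signal_strength Probability that a content token is drawn from the
#'   document's class lexicon rather than the shared vocabulary.
#' @param length_mean,length_sd,length_min,length_max Token-count
#'   distribution (normal, truncated to `[length_min, length_max]`).
#' @param emoji_rate Per-token probability of emitting an emoji (chosen from
#'   the document class's inventory with probability 0.8, the other with
#'   0.2).
#' @param signal_channel Where downstream experiments place the class
#'   signal: `"lexicon"` (the marker tokens themselves), `"embedding"`
#'   (embedding-space directions attached to the markers via
#'   [hash_backend()] signal mode, typically with the graph rewired) or
#'   `"both"`. The generator always plants the marker tokens; this field is
#'   provenance for the experiment wiring.
#' @param seed Integer seed.
#' @return A validated `synthetic_spec`.
#' @export
synthetic_spec <- function(n_docs, class_balance = 0.5, vocab_shared = 150L,
                           vocab_class = 30L, signal_strength = 0.5,
                           length_mean = 50, length_sd = 15,
                           length_min = 5L, length_max = 200L,
                           emoji_rate = 0.02,
                           signal_channel = c("lexicon", "embedding", "both"),
                           seed = 1L) {
  signal_channel <- match.arg(signal_channel)
  stopifnot(n_docs >= 2, class_balance >= 0, class_balance <= 1,
            vocab_shared >= 1, signal_strength >= 0, signal_strength <= 1,
            emoji_rate >= 0, emoji_rate <= 1,
            length_min >= 1, length_max >= length_min, length_mean > 0)
  if (vocab_class == 0 && signal_strength > 0) {
    stopf("class lexicon size 0 is incompatible with signal_strength > 0")
  }
  structure(list(n_docs = as.integer(n_docs), class_balance = class_balance,
                 vocab_shared = as.integer(vocab_shared),
                 vocab_class = as.integer(vocab_class),
                 signal_strength = signal_strength,
                 length_mean = length_mean, length_sd = length_sd,
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 emoji_rate = emoji_rate, signal_channel = signal_channel,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Corpus-shape presets
#'
#' `twitter_like_spec()` emulates short emoji-rich posts (mean 100 tokens,
#' emoji rate 0.05) with the 26.34% positive-class imbalance typical of
#' tweet-level depression corpora; `forum_like_spec()` emulates long forum
#' posts (mean 1,100 tokens, emoji rate 0.01, balance 0.3).
#'
#' @param n_docs Number of documents.
#' @param seed Integer seed.
#' @return A `synthetic_spec`.
#' @export
twitter_like_spec <- function(n_docs = 200L, seed = 1L) {
  synthetic_spec(n_docs = n_docs, class_balance = 843 / 3200,
                 vocab_shared = 200L, vocab_class = 30L,
                 signal_strength = 0.3, length_mean = 100, length_sd = 53,
                 length_min = 6L, length_max = 374L, emoji_rate = 0.05,
                 seed = seed)
}

#' @rdname twitter_like_spec
#' @export
forum_like_spec <- function(n_docs = 100L, seed = 1L) {
  synthetic_spec(n_docs = n_docs, class_balance = 0.3,
                 vocab_shared = 400L, vocab_class = 40L,
                 signal_strength = 0.2, length_mean = 1100, length_sd = 800,
                 length_min = 52L, length_max = 5717L, emoji_rate = 0.01,
                 seed = seed)
}

#' Class-marker lexicons of a spec
#'
#' The word lists the generator uses as class-specific lexicons, exposed so
#' experiments can hand them to [hash_backend()] signal mode.
#'
#' @param spec A `synthetic_spec`.
#' @return `list(positive, negative)` character vectors.
#' @export
signal_lexicons <- function(spec) {
  list(positive = sprintf("sadterm%03d", seq_len(spec$vocab_class)),
       negative = sprintf("calmterm%03d", seq_len(spec$vocab_class)))
}

#' Generate a synthetic labelled corpus
#'
#' Labels are allocated exactly (`round(n_docs * class_balance)` positive)
#' and shuffled; token counts follow the truncated normal of the spec; each
#' token position emits an emoji with probability `emoji_rate`
#' (class-conditional inventory), otherwise a class-lexicon word with
#' probability `signal_strength`, otherwise a shared-vocabulary word drawn
#' from a Zipf law (exponent 1.1). Deterministic given the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A labelled, untokenized `textgcn_corpus` (run
#'   [build_vocabulary()] before graph construction).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lex <- signal_lexicons(spec)
  shared <- sprintf("word%04d", seq_len(spec$vocab_shared))
  zipf_p <- (1 / seq_len(spec$vocab_shared)^1.1)
  zipf_p <- zipf_p / sum(zipf_p)
  # Recentre the sampling location so the *truncated* normal has mean
  # length_mean (asymmetric bounds would otherwise bias realized lengths).
  mu <- spec$length_mean
  for (it in 1:25) {
    a <- (spec$length_min - mu) / spec$length_sd
    b <- (spec$length_max - mu) / spec$length_sd
    shift <- spec$length_sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
    mu <- mu - ((mu + shift) - spec$length_mean)
  }
  local_seed(spec$seed, {
    n_pos <- round(spec$n_docs * spec$class_balance)
    labels <- integer(spec$n_docs)
    labels[sample(spec$n_docs, n_pos)] <- 1L
    lens <- integer(spec$n_docs)
    todo <- seq_len(spec$n_docs)
    for (it in 1:50) {                      # truncated-normal rejection
      if (!length(todo)) break
      draw <- round(rnorm(length(todo), mu, spec$length_sd))
      ok <- draw >= spec$length_min & draw <= spec$length_max
      lens[todo[ok]] <- draw[ok]
      todo <- todo[!ok]
    }
    if (length(todo)) {
      lens[todo] <- pmin(pmax(round(rnorm(length(todo), mu, spec$length_sd)),
                              spec$length_min), spec$length_max)
    }
    texts <- vapply(seq_len(spec$n_docs), function(d) {
      n <- lens[d]
      own <- if (labels[d] == 1L) lex$positive else lex$negative
      other_emo <- if (labels[d] == 1L) .emoji_negative else .emoji_positive
      own_emo <- if (labels[d] == 1L) .emoji_positive else .emoji_negative
      u <- stats::runif(n)
      toks <- character(n)
      is_emo <- u < spec$emoji_rate
      n_emo <- sum(is_emo)
      if (n_emo) {
        from_own <- stats::runif(n_emo) < 0.8
        toks[is_emo] <- ifelse(from_own,
                               sample(own_emo, n_emo, replace = TRUE),
                               sample(other_emo, n_emo, replace = TRUE))
      }
      rest <- !is_emo
      is_sig <- rest & (u >= spec$emoji_rate) &
        (stats::runif(n) < spec$signal_strength)
      is_sig[!rest] <- FALSE
      n_sig <- sum(is_sig)
      if (n_sig) toks[is_sig] <- sample(own, n_sig, replace = TRUE)
      n_sh <- sum(rest & !is_sig)
      if (n_sh) toks[rest & !is_sig] <- sample(shared, n_sh, replace = TRUE,
                                               prob = zipf_p)
      paste(toks, collapse = " ")
    }, character(1))
    corp <- corpus_from_texts(texts, labels)
    attr(corp, "spec") <- spec
    corp
  })
}

#' Write the spec alongside a generated corpus
#'
#' @param spec A `synthetic_spec`.
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_spec_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

# Double-edge-swap randomization of one edge family. Bipartite-safe: a swap
# (a-b),(c-d) -> (a-d),(c-b) keeps every endpoint on its own side, and for
# unipartite families self-loops / duplicate edges are rejected.
.rewire_edges <- function(edges, n_swaps, bipartite) {
  m <- nrow(edges)
  if (m < 2) return(list(edges = edges, swapped = 0L))
  key <- function(i, j) {
    if (bipartite) paste(i, j) else paste(pmin(i, j), pmax(i, j))
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(m)) seen[[key(edges$i[r], edges$j[r])]] <- TRUE
  swapped <- 0L
  for (s in seq_len(n_swaps)) {
    pick <- sample.int(m, 2L)
    a <- edges$i[pick[1]]; b <- edges$j[pick[1]]
    cc <- edges$i[pick[2]]; dd <- edges$j[pick[2]]
    ni1 <- a; nj1 <- dd; ni2 <- cc; nj2 <- b
    if (!bipartite && (ni1 == nj1 || ni2 == nj2)) next
    k1 <- key(ni1, nj1); k2 <- key(ni2, nj2)
    if (k1 == k2 || !is.null(seen[[k1]]) || !is.null(seen[[k2]])) next
    rm(list = c(key(a, b), key(cc, dd)), envir = seen)
    seen[[k1]] <- TRUE; seen[[k2]] <- TRUE
    edges$i[pick[1]] <- ni1; edges$j[pick[1]] <- nj1
    edges$i[pick[2]] <- ni2; edges$j[pick[2]] <- nj2
    swapped <- swapped + 1L
  }
  list(edges = edges, swapped = swapped)
}

# Extract one family's canonical edge list from the assembled adjacency.
.family_edges <- function(graph, kind) {
  Tm <- as(drop0(graph$A), "TsparseMatrix")
  ii <- Tm@i + 1L; jj <- Tm@j + 1L; w <- Tm@x
  D <- graph$D
  sel <- switch(kind,
    doc_doc = ii < jj & ii <= D & jj <= D,
    word_word = ii < jj & ii > D & jj > D,
    word_doc = ii > D & jj <= D)
  data.frame(i = ii[sel], j = jj[sel], weight = w[sel])
}

#' Degree-preserving randomization of the text graph
#'
#' Applies double-edge swaps independently within each edge family
#' (word--word, word--document, document--document), preserving every node's
#' degree within each family and the bipartite structure of the
#' word--document family, then shuffles the observed weights among the
#' surviving edges. This destroys label-correlated structure while keeping
#' the degree sequence, which makes it the ablation tool for separating
#' signal carried by graph structure from signal carried by node features.
#'
#' @param graph An assembled `textgcn_graph`.
#' @param seed Integer seed.
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @return A rewired, renormalized `textgcn_graph`. A family with fewer than
#'   two edges is returned unchanged with a warning.
#' @export
rewire_graph <- function(graph, seed, swaps_per_edge = 10) {
  local_seed(seed, {
    fams <- list(doc_doc = .family_edges(graph, "doc_doc"),
                 word_word = .family_edges(graph, "word_word"),
                 word_doc = .family_edges(graph, "word_doc"))
    out <- lapply(names(fams), function(kind) {
      e <- fams[[kind]]
      if (nrow(e) < 2) {
        if (nrow(e) > 0) warnf("family %s has too few edges to swap", kind)
        return(e)
      }
      res <- .rewire_edges(e, n_swaps = ceiling(swaps_per_edge * nrow(e)),
                           bipartite = (kind == "word_doc"))
      res$edges$weight <- sample(res$edges$weight)
      res$edges
    })
    names(out) <- names(fams)
    D <- graph$D
    g2 <- assemble_adjacency(
      new_edges(out$word_word$i - D, out$word_word$j - D,
                out$word_word$weight, "word_word"),
      new_edges(out$word_doc$i - D, out$word_doc$j,
                out$word_doc$weight, "word_doc"),
      new_edges(out$doc_doc$i, out$doc_doc$j, out$doc_doc$weight, "doc_doc"),
      D = D, M = graph$M, node_names = graph$node_names)
    g2$window_size <- graph$window_size
    g2$jaccard_threshold <- graph$jaccard_threshold
    normalize_adjacency(g2)
  })
}
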