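test_that("PMI matches hand-derived window counts on designed corpora", {
  # four one-window documents; a,b always co-occur: W=4, W(a)=W(b)=W(ab)=2
  corp <- toy_corpus(c("a b", "a b", "c d", "c d"))
  ww <- compute_pmi(corp, window_size = 2)
  ab <- ww[ww$i == corp$vocabulary["a"] & ww$j == corp$vocabulary["b"], ]
  expect_equal(ab$weight, log(2), tolerance = 1e-12)
  # words never sharing a window get no edge
  ac <- ww[ww$i == corp$vocabulary["a"] & ww$j == corp$vocabulary["c"], ]
  expect_equal(nrow(ac), 0L)
  # exactly independent pair: W(xy)/W == (W(x)/W)(W(y)/W) -> PMI 0, excluded
  # 2 windows of 2 tokens each from doc "x y x y" with window 2: W=3,
  # W(x)=3, W(y)=3... construct explicit independence instead:
  corp2 <- toy_corpus(c("x y", "x z", "w y", "w z"))
  ww2 <- compute_pmi(corp2, window_size = 2)
  xy <- ww2[ww2$i == corp2$vocabulary["x"] & ww2$j == corp2$vocabulary["y"], ]
  # W=4, W(x)=W(y)=2, W(xy)=1 -> PMI = ln(4/4) = 0, strict inequality drops it
  expect_equal(nrow(xy), 0L)
  expect_error(compute_pmi(corp, window_size = 0), "window_size")
})

test_that("PMI equals the exhaustive window-enumeration oracle", {
  for (seed in 1:8) {
    corp <- random_toy_corpus(seed)
    ids <- corpus_token_ids(corp)
    M <- vocab_size(corp)
    for (w in c(2L, 3L, 20L)) {
      orc <- oracle_pmi_dense(ids, M, w)
      ww <- compute_pmi(corp, w)
      P <- matrix(0, M, M)
      if (nrow(ww)) {
        P[cbind(ww$i, ww$j)] <- ww$weight
        P[cbind(ww$j, ww$i)] <- ww$weight
      }
      expect_equal(P, orc$P, tolerance = 1e-12)
    }
  }
})

test_that("duplicating every document leaves PMI values unchanged", {
  corp <- random_toy_corpus(42)
  texts <- corp$documents$raw_text
  corp2 <- toy_corpus(c(texts, texts))
  expect_identical(corp$vocabulary, corp2$vocabulary)
  ww1 <- compute_pmi(corp, 3)
  ww2 <- compute_pmi(corp2, 3)
  o1 <- order(ww1$i, ww1$j); o2 <- order(ww2$i, ww2$j)
  expect_equal(ww1$i[o1], ww2$i[o2])
  expect_equal(ww1$weight[o1], ww2$weight[o2], tolerance = 1e-12)
})

test_that("TF-IDF uses raw counts with unsmoothed idf", {
  # tf=2 in one doc, df=1, D=4 -> 2 ln 4
  corp <- toy_corpus(c("b b a", "a", "a", "a c"))
  wd <- compute_tfidf(corp)
  b <- wd[wd$i == corp$vocabulary["b"], ]
  expect_equal(nrow(b), 1L)
  expect_equal(b$j, 1L)
  expect_equal(b$weight, 2 * log(4), tolerance = 1e-12)
  # a word present in every document has idf 0 and no edges
  expect_equal(nrow(wd[wd$i == corp$vocabulary["a"], ]), 0L)
  # absent word-doc pairs yield no edge
  expect_equal(nrow(wd[wd$i == corp$vocabulary["c"] & wd$j != 4L, ]), 0L)
})

test_that("Jaccard similarity is exact on enumerated token sets", {
  corp <- toy_corpus(c("a b c", "b c d", "x y", "a b c"))
  dd <- compute_jaccard(corp)
  get <- function(i, j) {
    r <- dd[dd$i == min(i, j) & dd$j == max(i, j), ]
    if (nrow(r)) r$weight else 0
  }
  expect_equal(get(1, 2), 2 / 4)   # {a,b,c} vs {b,c,d}
  expect_equal(get(1, 4), 1)       # identical sets
  expect_equal(get(1, 3), 0)       # disjoint sets: no edge
  expect_equal(nrow(dd[dd$i == dd$j, ]), 0L)
  dd2 <- compute_jaccard(corp, threshold = 0.6)
  expect_equal(nrow(dd2), 1L)      # only the identical pair survives
})

test_that("assembled adjacency is symmetric, zero-diagonal and blockwise correct", {
  empty <- new_edges_for_test()
  g0 <- assemble_adjacency(empty$ww, empty$wd, empty$dd, D = 2, M = 3)
  expect_equal(sum(abs(g0$A)), 0)
  expect_equal(dim(g0$A), c(5, 5))

  wd <- structure(data.frame(i = 1L, j = 1L, weight = 1.5),
                  kind = "word_doc", class = c("textgcn_edges", "data.frame"))
  g1 <- assemble_adjacency(empty$ww, wd, empty$dd, D = 2, M = 1)
  expect_equal(g1$A[3, 1], 1.5)
  expect_equal(g1$A[1, 3], 1.5)

  dup <- structure(data.frame(i = c(1L, 1L), j = c(1L, 1L),
                              weight = c(1, 2)),
                   kind = "word_doc", class = c("textgcn_edges", "data.frame"))
  expect_error(assemble_adjacency(empty$ww, dup, empty$dd, D = 2, M = 1),
               "duplicate")
})

test_that("assembly equals the dense triple-loop oracle on toy corpora", {
  for (seed in 1:6) {
    corp <- random_toy_corpus(seed + 100)
    ids <- corpus_token_ids(corp)
    g <- build_graph(corp, window_size = 3)
    Ao <- oracle_adjacency_dense(ids, vocab_size(corp), window = 3)
    expect_equal(as.matrix(g$A), Ao, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(as.matrix(g$A), t(as.matrix(g$A)))
    expect_equal(unname(diag(as.matrix(g$A))), rep(0, g$n))
  }
})

test_that("normalization matches the closed form and keeps the spectrum in [-1, 1]", {
  # two nodes joined by weight 1: A_hat = [[.5,.5],[.5,.5]]
  wd <- structure(data.frame(i = 1L, j = 1L, weight = 1),
                  kind = "word_doc", class = c("textgcn_edges", "data.frame"))
  e <- new_edges_for_test()
  g <- normalize_adjacency(assemble_adjacency(e$ww, wd, e$dd, D = 1, M = 1))
  expect_equal(as.matrix(g$A_hat), matrix(0.5, 2, 2), ignore_attr = TRUE)

  # isolated node: identity row
  g2 <- normalize_adjacency(assemble_adjacency(e$ww, e$wd, e$dd, D = 2, M = 1))
  expect_equal(as.matrix(g2$A_hat), diag(3), ignore_attr = TRUE)

  for (seed in 1:5) {
    g3 <- random_normalized_graph(20, seed)
    Ah <- as.matrix(g3$A_hat)
    expect_equal(max(abs(Ah - t(Ah))), 0)
    ev <- eigen(Ah, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-9 & ev <= 1 + 1e-9))
    expect_equal(Ah, oracle_normalize_dense(as.matrix(g3$A)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # row action on the all-ones vector reproduces sum_j At_ij/sqrt(d_i d_j)
    At <- as.matrix(g3$A) + diag(g3$n)
    d <- rowSums(At)
    closed <- sapply(seq_len(g3$n), function(i) sum(At[i, ] / sqrt(d[i] * d)))
    expect_equal(as.numeric(Ah %*% rep(1, g3$n)), closed, tolerance = 1e-12)
  }
})

test_that("graph exports carry the symmetric storage contract", {
  corp <- toy_corpus(c("a b c", "b c d", "a d"))
  g <- build_graph(corp, window_size = 2)
  d <- tempfile()
  write_graph_mtx(g, d)
  write_edge_tsv(g, file.path(d, "edges.tsv"))
  write_node_map_tsv(g, file.path(d, "nodes.tsv"))
  A2 <- Matrix::readMM(file.path(d, "A.mtx"))
  expect_equal(as.matrix(A2), as.matrix(g$A), tolerance = 1e-12,
               ignore_attr = TRUE)
  edges <- read.delim(file.path(d, "edges.tsv"))
  expect_equal(2L * nrow(edges), length(Matrix::drop0(g$A)@x))
  expect_equal(sort(unique(edges$kind)),
               sort(names(which(g$edge_counts > 0))))
  nodes <- read.delim(file.path(d, "nodes.tsv"))
  expect_equal(nrow(nodes), g$n)
  expect_equal(sum(nodes$kind == "doc"), g$D)
})
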