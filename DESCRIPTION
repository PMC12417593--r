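Package: textgcn
Title: Text Graph Convolutional Networks for Depression Detection in
    Social-Media Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transductive text classification over a heterogeneous
    word-document graph, aimed at detecting depression-indicative posts in
    social-media corpora. Builds the graph with pointwise mutual information
    (word-word), TF-IDF (word-document) and Jaccard (document-document)
    edge weights, initializes node features either as one-hot vectors or as
    emotion representations from a pluggable token-embedding backend
    (CLS-style document vectors, min-pooled word vectors), and classifies
    document nodes with a two-layer graph convolutional network trained by
    Adam with early stopping. Includes an emoji-preserving tokenizer, a
    synthetic labelled-corpus generator for controlled benchmarking,
    cross-validated evaluation with paired t-tests, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
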