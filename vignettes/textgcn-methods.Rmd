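---
title: "Graph convolutional text classification for depression detection: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph convolutional text classification for depression detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(textgcn)
```

## The problem and the model

Depression-indicative language in social-media posts is a weak, distributed
signal: affect-bearing words, emojis and emoticons scattered through text of
wildly varying length. `textgcn` approaches detection as *transductive node
classification* on a single heterogeneous graph built over the whole corpus.
The node set contains every document and every vocabulary word, so with $D$
documents and $M$ retained words the graph has $n = D + M$ nodes.

Three edge families carry three kinds of co-occurrence information:

* **word–word**: pointwise mutual information over sliding windows,
  $\mathrm{PMI}(i,j) = \ln \frac{W(i,j)/W}{(W(i)/W)\,(W(j)/W)}$,
  where $W$ is the total window count, $W(i)$ the windows containing word
  $i$ and $W(i,j)$ the windows containing both. Only strictly positive PMI
  values become edges — a pair at exact statistical independence
  ($\mathrm{PMI}=0$) is excluded.
* **word–document**: TF-IDF, $tf(w,d)\,\ln(D/df(w))$ with raw counts and an
  unsmoothed idf, so a word present in every document contributes nothing.
* **document–document**: Jaccard similarity of the documents' retained token
  sets, $|S_i \cap S_j| / |S_i \cup S_j|$, kept when strictly above a
  threshold (default 0).

The adjacency matrix $A$ is symmetric with zero diagonal; self-connections
enter only through the normalization
$\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}$ with
$\tilde D_{ii} = \sum_j (A+I)_{ij}$. Because every node gains a self-loop,
degrees are at least one and the spectrum of $\hat A$ lies in $[-1, 1]$,
which keeps repeated propagation numerically stable.

Classification uses a two-layer graph convolution,
$$H^{(1)} = \mathrm{ReLU}(\hat A H^{(0)} W^{(0)}), \qquad
Z = \mathrm{softmax}(\hat A H^{(1)} W^{(1)}),$$
trained by minimizing the cross-entropy over the labelled document nodes.
Test documents are present in the graph as unlabelled nodes during training
(the transductive protocol); their labels never touch the loss, but their
text does shape the graph. This is a known source of indirect supervision
leakage inherent to the design; `rewire_graph()` provides the ablation tool
for quantifying how much of the performance rides on graph structure at all.

## Node features

Two feature sources initialize $H^{(0)}$:

* `onehot_features(n)` — the sparse $n \times n$ identity. All class signal
  must then flow through the graph.
* `backend_features(corpus, backend)` — "emotion representations" from any
  embedding backend satisfying a small contract: given a token sequence it
  returns one sequence-summary vector (a CLS-style representation, used as
  the document-node feature) and one vector per input token. Word-node
  features pool the vectors of *all* occurrences of the word across the
  corpus; the default reduction is the elementwise **minimum**, implemented
  literally as stated (an unusual choice — mean and max are available
  alternatives, and the min is deliberately not reinterpreted).

Documents longer than the backend's position limit are split into
consecutive chunks; the document vector is the mean of the chunk summaries
and token vectors are concatenated, so no token is lost to truncation and
every occurrence still participates in word pooling. Backends wrapping
subword tokenizers are responsible for returning vectors aligned to the
input tokens (mean-pooling subword pieces); the shipped `hash_backend()`
works on whole tokens and needs no alignment. Which transformer layer
supplies token vectors is a property of the backend adapter, not of this
package; the contract only requires determinism.

`hash_backend(dim, seed)` is a deterministic stand-in backend: token vectors
are seeded hashes in $[-1,1]^{dim}$, the sequence vector is their mean, and
*signal mode* adds a fixed class-direction vector to tokens from a given
lexicon. It exists so that the entire feature pipeline is testable and so
that class signal can be planted purely in embedding space for ablation
experiments. It is not a language model and makes no claim to semantics.

## Tokenization

Emojis and ASCII emoticons are retained as individual tokens, never split
or dropped: multi-codepoint emoji sequences (skin tones, ZWJ sequences)
match as one token, and a shipped emoticon lexicon (`emoticon_lexicon()`)
is matched longest-first before the word pattern. Lowercasing applies to
word tokens only (case-folding `":D"` would corrupt it). URLs and
`@mentions` become sentinel tokens `<url>` / `<user>` by default. Stopword
removal is off by default because negations are affect-bearing; the
built-in list excludes them. The vocabulary keeps words with document
frequency at least `min_df` (default 5, the customary pruning level for
word–document graph classifiers; small corpora should lower it), indexed
by first occurrence so the word-index bijection is reproducible.

## Training

Full-batch Adam (learning rate 0.02, up to 200 epochs), hidden width 200,
dropout 0.5 on layer inputs, two layers — the defaults of
`train_config()`. A stratified 10% of the training documents is held out to
monitor validation loss; training stops after 10 epochs without improvement
and returns the best-validation parameters. Weights use Glorot-uniform
initialization under a recorded seed; forward, backward and Adam are
implemented directly on sparse matrix algebra, and with a fixed seed the
whole run is bit-reproducible (all randomness flows through R's RNG, which
the package saves and restores around every seeded operation). The loss is
the *mean* over masked documents rather than the sum — equivalent up to a
rescaling of the learning rate, and more stable when the labelled set size
varies across folds. Predicted labels are the row argmax of $Z$; an exact
tie goes to class 0 (non-depression), a deliberate conservative choice.

`hyperparameter_search()` walks a grid of layer counts {2,3,4,5}, hidden
widths {100..500}, dropout {0.01,0.05,0.1,0.5}, learning rates
{0.01..0.05} and weight decays {0,0.005,0.05} — 1,200 configurations —
either exhaustively or by random subsampling, scoring each trial on a fixed
stratified validation carve-out. Layer counts above two stack additional
propagation layers with ReLU between and softmax last.

## Evaluation

`confusion_counts()` treats depression (label 1) as the positive class;
accuracy, precision, recall and F1 follow the standard closed forms, with
zero-denominator ratios reported as 0 with a warning (degenerate folds on
imbalanced corpora do occur). `crossvalidate()` builds the graph once and
rotates each fold out of the training mask — the transductive analogue of
K-fold CV — aggregating by unweighted means. `paired_ttest()` compares two
models' per-fold metric vectors with a two-sided paired t-test (the fold is
the pairing unit, the only repeated measurement the protocol produces);
stars follow the conventional thresholds (\*, \*\*, \*\*\* at 0.05, 0.01,
0.001). One test is run per (model, metric) pair. Degenerate cases are
defined, not left to chance: all-zero differences give $p=1$; zero-variance
nonzero differences give $p=0$ with a flag. No multiple-testing correction
is applied across the model × metric grid.

## The synthetic generator

`generate_corpus()` emulates binary-labelled post corpora well enough to
exercise every code path: a Zipf-weighted shared vocabulary (exponent 1.1,
mimicking natural-text tails), disjoint class-marker lexicons entered with
probability `signal_strength`, class-conditional emoji injection, and
token counts from a truncated normal. The sampling location is recentred so
the *truncated* distribution has the requested mean — with asymmetric
bounds the naive draw would bias realized lengths upward. Label allocation
is exact (`round(n_docs * balance)`) and shuffled. Presets mirror the two
regimes of real depression corpora: `twitter_like_spec()` (mean 100
tokens, sd 53, emoji rate 0.05, 26.34% positive) and `forum_like_spec()`
(mean 1,100 tokens, emoji rate 0.01).

The `signal_channel` field records how an experiment uses the class
markers. The generator always plants them — a corpus whose token
distribution is class-independent cannot carry class signal into
token-identity features at all — and the channels differ downstream:
`"lexicon"` lets the markers act through graph structure and one-hot
features; `"embedding"` attaches embedding-space directions to the markers
via `hash_backend()` signal mode, typically combined with `rewire_graph()`
(degree-preserving double-edge swaps within each edge family, bipartite
structure respected, weights shuffled among surviving edges) to destroy the
structural route. With `signal_strength = 0` and `emoji_rate = 0` the two
classes are distributionally identical.

What passing tests on this generator do **not** show: robustness to real
depressive language (sarcasm, self-negation, code-switching, platform
slang), to annotation noise, or to distribution shift between platforms.
The generator's separability is controlled and honest about being
synthetic; results on it bound software correctness, not clinical utility.

## Numerical choices and degenerate inputs

* Natural logarithm everywhere (PMI, idf, cross-entropy); base changes only
  rescale weights uniformly within an edge family.
* A non-empty document shorter than the PMI window contributes exactly one
  window; a document whose tokens were all filtered out contributes none.
* Probabilities are clamped at $10^{-12}$ before logs; a perfect prediction
  has exactly zero loss.
* An isolated node normalizes to an identity row in $\hat A$ (degree 1 from
  its self-loop); empty edge sets assemble to a zero adjacency.
* Two empty token sets have Jaccard similarity 0 by convention.
* Conflicting duplicate weights for one node pair abort assembly — they can
  only arise from a builder bug, never from the three disjoint families.

## Problem sizes

The shipped tests and the acceptance script run on corpora of 40–500
documents with vocabularies of tens to hundreds of words, training for at
most 200 epochs — sizes chosen so the full suite exercises every path,
including 5-seed ablations and a 1,000-repetition t-test calibration, in a
couple of minutes on one CPU. The implementation itself is sparse
throughout and scales to corpora orders of magnitude larger; PMI window
counting is the step that grows fastest (windows × pairs per window) and is
aggregated incrementally per document.

## Known limitations

* Transductive only: classifying a new document requires rebuilding the
  graph. Inductive extension is a non-goal here.
* The embedding backends of interest (mental-health domain-adapted
  transformers) are external: they bind to the backend contract as
  configuration, and this package ships only the deterministic hash
  backend. No fine-tuning or joint training is provided.
* Class imbalance is not reweighted by default; degenerate-fold metric
  conventions make that visible rather than hiding it.
* Emojis are retained as tokens but not mapped to affect-aware embeddings;
  they are ordinary vocabulary entries.
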