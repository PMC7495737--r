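---
title: "Methods: hierarchical attention capsule networks for document triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical attention capsule networks for document triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captriage)
```

## The problem

Literature curation pipelines (for example, cataloguing protein–protein
interactions affected by genetic mutations, PPIm) begin with *document
triage*: a binary decision, per PubMed citation, of whether its title and
abstract are relevant to the curation task. Abstracts are long,
multi-sentence, and terminology-dense, so the discriminative evidence is
spread across sentences. `captriage` implements a classifier designed for
exactly this structure.

## Model

A document is split into sentences and tokens, embedded, and passed through
four stages.

**Word-level multi-head self-attention.** For one sentence with token
matrix $X$, each head $i$ computes

$$\mathrm{Attention}(Q,K,V) = \mathrm{softmax}\!\left(QK^\top/\sqrt{d_k}\right)V,
\qquad Q = XW_i^Q,\; K = XW_i^K,\; V = XW_i^V,$$

and the $h$ head outputs are concatenated and reprojected by $W^O \in
\mathbb{R}^{h d_v \times d_{\mathrm{model}}}$. With the default geometry
(8 heads of dimension 32 over 200-dimensional embeddings) the
concatenation is 256-wide and $W^O$ maps it back to 200, so the layer
preserves the embedding width regardless of head geometry. The attended
token vectors of a sentence are pooled into one sentence vector, either by
a masked mean (the default: parameter-free, keeps the attention's
reweighting effect) or by a learned pooling query (`pool = "query"`): a
trainable vector scores each token and the sentence vector is the
softmax-weighted token sum. The mean dilutes a rare cue token by sentence
length; the learned query can concentrate on it, which measurably sharpens
count-like evidence (see the reduced profile below).

**Sentence-level self-attention.** The same multi-head mechanism is applied
across the document's sentence vectors, producing an attended sentence
sequence. This two-level arrangement is what lets the model relate
evidence in different sentences without paying the quadratic cost of
token-level attention over the whole document.

**Parallel convolution.** For each window width $w \in \{3,4,5\}$ the model
computes $S_t = \mathrm{ReLU}(W x_{t:t+w-1} + b)$ at every sentence
position under same-length zero padding, and splices the per-window
feature maps (128 each, 384 total). Stride is 1; padding preserves the
position count so the capsule stage sees one feature vector per sentence.

**Capsule layers with dynamic routing.** The convolution features at each
position are cut into groups of 32 and squashed,

$$v = \frac{\lVert s\rVert^2}{1+\lVert s\rVert^2}\,\frac{s}{\lVert s\rVert},$$

giving primary capsules whose norms lie in $[0,1)$. Each child capsule
$u_i$ predicts each parent through $\hat u_{j|i} = W_{ij} u_i$ (transforms
shared across positions per child type). Routing-by-agreement runs $r = 3$
iterations: couplings $c_{ij} = \mathrm{softmax}_j(z_{ij})$ start uniform
($z = 0$), parents form $s_j = \sum_i c_{ij}\hat u_{j|i}$ and $v_j =
\mathrm{squash}(s_j)$, and logits grow by the agreement $\hat u_{j|i}
\cdot v_j$ (skipped after the final iteration). Ten parent capsules of
dimension 32 feed a 100-unit ReLU dense layer and a 2-way softmax.

Training minimizes categorical cross-entropy with Adam (default learning
rate 0.01, batch size 128, 50 epochs), with dropout 0.5 before the word
representation layer and 0.8 before the output layer. Since the published
description does not bind each dropout value to a site or specify drop-
versus-keep semantics, both are independent config fields interpreted as
drop probabilities. 10% of the training corpus is held out as a
development set and per-epoch train/dev loss and dev P/R/F1 are logged.

## Numerical and design choices

* **Masked softmax.** Pad positions get $-10^9$ added to their logits
  before normalization, which forces their weight to zero without
  special-casing the gradient. Inside the model the per-sentence token
  slices are dense (tokens are left-aligned), so masking reduces to
  slicing; the exported operations accept explicit masks.
* **Squash at zero.** The norm is computed as $\sqrt{\lVert s\rVert^2 +
  \varepsilon}$ with $\varepsilon = 10^{-8}$, removing the undefined
  direction at $s = 0$ with bias far below any tolerance used here.
* **Routing state is not a parameter.** Coupling coefficients are
  recomputed from zero logits on every forward pass and are treated as
  constants during backpropagation (the gradient flows through
  $s_j = \sum_i c_{ij} \hat u_{j|i}$ with $c$ fixed). At $r = 1$ the
  couplings are exactly the constant uniform softmax, so the analytic
  gradient is exact there — which is how the package's gradient check is
  posed. At $r > 1$ this is the standard detached-routing approximation;
  its relative deviation from a full unrolled derivative is of order
  $10^{-4}$ on micro models, and it is the form under which the model is
  trained.
* **Embedding initialization.** Pretrained vectors (word2vec text format)
  are copied when supplied; without them, embeddings start at
  $\mathcal{N}(0, 1/\sqrt{d})$ per coordinate — unit-norm tokens in
  expectation, the scale word2vec itself produces. A smaller scale (for
  example uniform on $[-0.05, 0.05]$, which is retained for
  out-of-vocabulary rows when loading pretrained files) starves the
  doubly-squashed capsule path: with token norms near $0.05$ the class
  capsules shrink to $\sim 10^{-8}$ and every ReLU in the head is dead at
  initialization.
* **Gradient clipping.** Batch gradients are rescaled to a configurable
  global-norm ceiling (`clip_norm`, off by default, 1 in the reduced
  profile) to stabilize the last epochs at small batch sizes.
* **Epoch selection.** `select = "final"` (default) returns the
  final-epoch parameters; no early stopping is applied, matching the
  method's original training description. The alternative
  `select = "best_dev"` returns the epoch with the best development F1.
  It is not the default because F1-maximizing selection is biased on
  weak-signal corpora: predicting everything positive bounds dev F1 below
  by $2p/(1+p)$ at positive fraction $p$ (0.667 on balanced data), so on
  corpora with little to learn the selected state drifts toward the
  positive class. We measured exactly this on null synthetic corpora:
  best-dev selection yields held-out F1 pinned near 0.667 across seeds,
  while final-epoch selection behaves like a chance-level classifier.
* **Prediction ties** go to the negative class (documented argmax rule).
* **Degenerate inputs.** Records with no text after cleaning are dropped
  with a warning; a document whose every sentence fails the noise filter
  is a record-level error; an all-pad sentence encodes to the zero vector.

## Preprocessing

Sentence boundaries are found before punctuation stripping, with a
rule-based splitter (`[.?!]` followed by whitespace and a capital letter or
digit) — reproducible with no model downloads. Cleaning keeps only letters
and digits; tokens are lowercased to match standard word2vec vocabularies.
Sentences with fewer than `min_tokens = 2` tokens are dropped as noise
(the removal criterion is otherwise unspecified in the source material;
the threshold is configurable). Documents are truncated to 30 sentences
of 50 words by default, which covers typical abstracts. Vocabulary
indices are deterministic: frequency descending, ties lexicographic, with
index 0 reserved for `<PAD/>` and 1 for out-of-vocabulary. Labels encode
negative as 0 and positive as 1 throughout; unlabeled records are allowed
only at prediction time.

The corpus readers accept the two BioCreative dialects: the PM JSON form
(passages typed title/abstract, relevance under `relevant`, PMID under
`id`) and the IAS/ACT XML-like form (label under `CURATIONRELEVANCE`).
Title and abstract are concatenated in corpus order with a single space;
the dialects carry no weighting that would distinguish them.

## The synthetic-corpus generator

`synthetic_spec()` describes corpora with a planted, tunable class signal:
background tokens follow a Zipf distribution over a synthetic vocabulary
(realistic frequency profile, exercising out-of-vocabulary and frequency
ordering); signal keywords — stand-ins for strong relevance cues like
"mutation" and "interaction" — are inserted per sentence with
class-conditional rates; labels can be flipped with a noise probability.
Defaults: 400 documents, half positive, vocabulary of 100 background
tokens, planting rates 0.8 (positive) versus 0.05 (negative), 4–8
sentences of 4–10 words, no label noise — sized so a desk-scale model
can be trained on it in seconds per epoch while the Bayes-optimal rule
(roughly "two or more signal tokens") still leaves a nontrivial margin.
`generate_hard_negatives()` adds negatives that carry signal keywords at
the positive rate plus a subtler suppressor cue, reproducing the
characteristic false-positive pattern of keyword-matching classifiers.

What the generator does *not* emulate: real biomedical syntax, topical
correlation between background tokens, class imbalance at corpus scale,
and annotation guidelines. Passing the learnability checks on this data
shows the architecture, gradients and training loop work end to end; it
does not certify performance on real corpora.

## Problem sizes used in the checks

The package's own test suite and acceptance script run a reduced geometry
(`triage_config_small()`): 16-dimensional embeddings, 2 heads of dimension
8 per attention level, windows 2/3 with 8 maps each, capsule dimension 4
routed to 4 parents over 3 iterations, a 16-unit head, learned-query
pooling, batch size 16, 10 epochs, no dropout, and Adam at 0.02 decayed by
0.87 per epoch under gradient clipping at norm 1. These training settings
were chosen by a seed-robustness study on the default synthetic corpus:
query pooling lets the model recover the count-like Bayes rule that mean
pooling length-dilutes; the high-then-decayed rate learns the rule early
and leaves a settled final state; dropout is off because at this scale it
suppresses the per-document variation that keeps predictions on a
signal-free corpus at chance level instead of collapsing to one class. On
the default corpus (400 documents, 25% held out) training takes well under
a minute and reaches held-out F1 above 0.95; on the matched null corpus
(equal planting rates) predictions stay at chance. The held-out set is 100
documents, so the F1 estimate itself carries a standard error of roughly
0.015 — occasional excursions just below a fixed threshold are sampling
noise, not model changes. The gradient check runs on a micro geometry (all
dimensions at most 4, two documents) where central differences are
trustworthy; its fixture shifts the ReLU biases away from zero because a
finite-difference probe across a kink is meaningless.

## Known limitations

* Training is plain R; the full-size configuration (200-d embeddings, 384
  feature maps) is practical only for corpus-scale experiments with
  patience — the package's value at full scale is with pretrained
  embeddings and modest epoch counts.
* The attention layers are single (one per level), without residual
  connections, layer normalization, or positional encoding by default
  (a sinusoidal option exists behind `positional = TRUE`); a recurrent
  sentence encoder variant is not implemented.
* Routing gradients use the detached-coupling approximation described
  above.
* The parent-capsule count before the dense head (10 by default) is a
  convention, not a published value; it is configurable.
* Margin loss, reconstruction regularizers, EM routing, ensembling and
  post-processing of predictions are out of scope.
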