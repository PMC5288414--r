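---
title: "Screening for ASD from scanned medical forms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for ASD from scanned medical forms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Autism spectrum disorder (ASD) diagnosis is slow and expert-bound, while
the raw material for a first triage — referral forms, parent and teacher
questionnaires, intake notes — already exists for every referred child.
`asdscreen` implements a screening pipeline over that material: scanned
hand-written forms are de-skewed and de-identified, their transcribed
text is embedded as lexical, topic or paragraph-vector features, the
minority (ASD-positive) class is augmented by interpolation upsampling,
and a regularised squared-hinge linear SVM is evaluated under stratified
nested cross-validation. Because screening must not miss true cases, the
pipeline is tuned and reported with the recall-weighted F2 score,
`5·P·R / (4·P + R)`, rather than accuracy or F1.

The clinical corpora such a pipeline targets are confidential, so the
package ships generators (`simulateFormImage()`, `simulateCorpus()`)
that reproduce the *structure* of the data — pages with skewed text
lines and a personal-information block, and labelled two-class corpora
at the study imbalance of 56 positive to 143 negative documents — with
full ground truth, making every stage testable end to end.

## Image preprocessing

**De-skew by entropy minimisation.** A binarized page rotated by a
candidate angle α yields a row profile `P_α(x_i)`: the black-pixel
fraction of each pixel row. The de-skew criterion is the entropy
`H = −Σ P log P` over rows with at least 10% black pixels; rows below
10% are excluded because text rows sit well above that level while
pepper noise sits below it. Aligned text concentrates ink into few
high-fraction rows and minimises H, so the estimated corrective angle is
the grid minimiser. Numerical choices:

* Natural logarithm (any base has the same argmin).
* Two-stage grid: a coarse 1° pass over ±20°, then a fine pass at
  `stepDeg` within 1° of the coarse optimum. Ties break toward the
  smallest |α|, then toward the negative angle, so a flat entropy
  plateau yields the most conservative correction.
* The profile is computed on the fully rotated raster
  (nearest-neighbour for binary pages, preserving {0,1}; bilinear for
  grayscale; white border fill), not on a sheared projection, and
  rotation borders are not cropped.
* A blank page (no ink) returns angle 0 with a warning.

On the synthetic 480×360 forms, nearest-neighbour resampling quantises
the profile: edge displacement across a half-line-width of ~150 px
changes the raster only about every 0.2°. The recovery property is
therefore run at `stepDeg = 0.2` — a finer step only walks a plateau at
this raster size — while the CLI default stays 0.1°, appropriate for
real scans an order of magnitude larger. With that step, the estimate
lands within twice the grid step of the true angle on ≥ 95% of 100
seeded forms at |skew| ≤ 15° and 1% noise.

**De-identification.** Semi-structured referral forms carry personal
information above a strong horizontal separator. The marker row is the
row of maximal summed Sobel gradient energy (pair of 3×3 kernels,
replicated borders) within the top half of the page; everything above
it is painted black. The energy floor below which the marker is
declared "not found" defaults to an average gradient of 1 per pixel —
far above blank-page noise, far below a ruled line's response of ~4 per
pixel. Unstructured forms take a user-supplied JSON mask instead,
mirroring manual redaction practice.

## Document representations

* **Lexical.** Tokens are lower-cased alphabetic runs with a 174-word
  standard English stop list removed (replaceable by a user file); no
  stemming or spelling correction. Families: bag-of-words counts,
  bigram+trigram counts (one combined family), and tf-idf with
  `idf = ln(N / (1 + df))`. The +1 smoothing is kept exactly as
  defined, so a term present in every document has negative idf — a
  deliberate fidelity choice, asserted in the tests. Vocabularies carry
  every training term (no frequency cutoff) and are built on training
  folds only; held-out documents are projected onto them.
* **Topics.** LDA fitted by collapsed Gibbs sampling (symmetric priors,
  defaults α = 50/K, β = 0.01), deterministic given a seed. The
  document embedding averages the word-topic posteriors P(t|w) of the
  document's in-vocabulary tokens ("word-avg"); the more common
  per-document posterior reading is exposed as
  `method = "doc-posterior"` since the underlying description admits
  both. OOV tokens are skipped; empty documents embed as uniform.
* **Paragraph vectors.** CBoW and PV-DM trained from scratch with the
  *full softmax* over the vocabulary — exact rather than approximate,
  tractable at the vocabulary sizes this package targets — and
  *concatenated* context blocks (2c word vectors, plus the paragraph
  vector in PV-DM), zero-padded at document edges. Held-out documents
  get vectors by gradient ascent on a fresh paragraph vector with the
  word matrices frozen, so cross-validation never leaks test text into
  training. Gradients are verified against central finite differences
  at < 1e-4 relative error.

Training uses plain SGD in document order with a linearly decaying
learning rate, deterministic given the seed. On desk-scale corpora the
full-softmax objective needs a larger initial learning rate than
large-corpus word2vec practice: the package default is 0.025 over 50
epochs, and the test suite's end-to-end runs use lr 0.15 over 15
epochs at dimension 16, which separates the synthetic classes cleanly
in seconds.

## Imbalance correction

For each real positive sample, `nPerPositive` artificial positives are
drawn uniformly on the segments to its k nearest positive neighbours
(Euclidean metric; ties by index; k defaults to `nPerPositive` = 2, one
sample per neighbour, since the method fixes "nearest neighbours" but
not k). Artificial rows are flagged by provenance, lie in the convex
hull of the real positives, and are generated *inside each training
fold only* — an explicit honesty requirement checked by the leakage
audit. At the study imbalance this turns 56 positives into 168 against
143 negatives.

## Classifier and evaluation

The classifier minimises `‖w‖₁ + C Σ max(0, 1 − y·wᵀx)²` for
high-dimensional lexical features (sparsity) and
`½wᵀw + C Σ max(0, 1 − y·wᵀx)²` for dense topic/embedding features;
each `FeatureMatrix` carries a penalty hint so the routing is
automatic. The solver is proximal gradient descent (soft-thresholding
for L1) with backtracking line search, so the objective is
non-increasing by construction; on small instances it matches a
Nelder-Mead reference optimum within 1e-3 relative. The bias is a
constant-one feature regularised with the rest. Prediction breaks the
`wᵀx = 0` tie toward the positive class, favouring recall.

Evaluation is stratified 7-fold outer cross-validation with 5-fold
inner selection of C by mean F2 over `C ∈ {2⁻⁵, 2⁻³, …, 2⁵}` (smaller C
on ties). Headline metrics pool the confusion counts over outer folds;
per-fold metrics are also emitted. Inner folds re-upsample their own
training portions; the outer-train featurization (vocabulary, topic
model, embedding) is reused across inner splits rather than refitted —
the residual leakage affects only the choice of C, not the reported
test predictions, and keeps the run inside desk-scale budgets.

## The synthetic generators

`simulateFormImage()` builds a white page with a word-patterned
personal-information band, a solid two-row marker line, and 14
word-patterned text lines (6 px tall, 8 px gaps), rotates it about its
centre with the *same* rotation primitive the preprocessing uses (no
convention mismatch), then flips pixels with symmetric salt-and-pepper
noise. Ground truth records the angle, marker row and redaction
region.

`simulateCorpus()` draws each document from a mixture of
`nTopicsTrue` topic-word distributions with disjoint vocabulary
blocks; a document's topic proportions come from a symmetric Dirichlet
tilted per class by `exp(±divergence)`. Divergence 0 makes the two
classes statistically identical (a negative control asserted by a
permutation test); divergence ≥ 6 confines each class to its own
topics and hence essentially its own vocabulary, the regime where a
linear separator must succeed. Defaults fix the study conditions:
56 positive and 143 negative documents. Mean document length (default
120 tokens, Poisson) and vocabulary size (default 200) are realistic
for concatenated per-patient form text; the test suite runs shorter
documents (40–80 tokens) and smaller vocabularies to keep the full
suite in minutes.

What the generators do *not* emulate: handwriting, OCR error patterns,
form typography, page warp/distortion (only rigid rotation), topic
correlation, or realistic word frequency tails. Passing tests
therefore demonstrate correctness of the algorithms under controlled
structure, not clinical performance; published numbers from the
confidential 199-patient corpus are only checked where they are pure
arithmetic (the F2 round-trips from printed precision/recall).

## Degenerate inputs and edge rules

Blank pages warn and de-skew by 0°; out-of-bounds redaction regions
error; empty documents tokenize to empty vectors, embed as uniform
topic vectors, and infer zero paragraph vectors with a warning;
single-class training sets and folds missing a class error loudly
(naming the fold); `k ≥ m` neighbour requests and sub-2-positive
upsampling error; redaction and region blanking are idempotent.

## Problem sizes used by the shipped checks

Skew recovery: 100 forms at 480×360 px. Topic recovery: 30 documents,
vocabulary 40, 2 topics, 500 Gibbs sweeps, cosine ≥ 0.95 after
matching. Solver optimality: 40 random instances (n ≤ 50, d ≤ 5), gap
≤ 1e-3. End-to-end: the 56:143 corpus with vocabulary 120 and mean
length 60, doc2vec (dim 16, window 2) + L2 SVM under 7×5 nested CV,
with and without upsampling — the upsampled run must match or beat the
plain run on pooled recall. These sizes are the package's chosen
operating points for fast, deterministic verification; the functions
themselves accept study-scale inputs unchanged.

## Known limitations

* Entropy de-skew assumes roughly horizontal line structure; rotated
  tables or pages dominated by images can defeat it.
* The marker heuristic finds the *strongest* horizontal edge in the
  searched band; forms whose personal block lacks a separator need the
  manual mask route.
* Full-softmax embedding training is quadratic in vocabulary size per
  token and is not meant for vocabularies beyond a few thousand terms.
* The upsampler interpolates in feature space; for sparse counts the
  artificial rows are dense convex combinations, which is standard but
  means "documents" that no tokenizer would produce.
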