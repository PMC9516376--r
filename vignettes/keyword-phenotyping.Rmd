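---
title: "Keyword-guided phenotyping of long clinical documents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keyword-guided phenotyping of long clinical documents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

Rare adverse events such as severe drug hypersensitivity reactions (DHRs —
anaphylactic shock, drug-induced hypersensitivity syndrome, Stevens-Johnson
syndrome, epidermolysis bullosa) are massively under-reported through
spontaneous reporting systems, yet their symptoms and signs are written down
in the free-text notes of electronic health records. Finding those cases is a
*phenotyping* problem: classify each hospital visit's concatenated notes into
one of a few phenotype classes, with a designated *fallback* class (`NEG`, or
`UNKNOWN` for the smoking-status task) meaning "no evidence".

The obstacle is document length. One inpatient visit easily produces
thousands of Chinese characters of notes — far beyond the fixed input window
(typically 512 tokens) of standard contextual text encoders. notephen
implements a pipeline built around the observation that for guideline-defined
phenotypes, *a few key sentences carry essentially all of the signal*:

1. **Key-sentence selection.** Split the document into sentences and keep
   exactly those containing a task keyword. Keywords come from three sources:
   a hand-picked list of medical terms from the clinical guidelines defining
   each phenotype (shipped for the DHR task, 46 Chinese/abbreviation terms),
   the classic 7-unigram smoking list, or an unsupervised TF-IDF derivation
   (below).
2. **Document embedding.** Turn the (selected) text into one fixed-dimension
   vector. Three interchangeable backends: `truncate_encoder` (first
   `max_tokens` tokens through an external pretrained encoder),
   `hierarchy_mean` (every sentence encoded separately, vectors averaged —
   the unweighted mean, the strongest aggregate in prior phenotyping work),
   and `hash_ngram` (hashed character 1–3-gram counts, L2-normalized), a
   deterministic encoder that needs no pretrained weights. External encoders
   plug in via `register_encoder()` and are used as-is, without fine-tuning.
3. **Classification.** A one-vs-rest statistical classifier on the document
   vectors — support-vector classification (libsvm via e1071) or a linear
   model trained by averaged minibatch SGD — with hyperparameters chosen by
   an automatic grid search under stratified 10-fold cross-validation, scored
   by micro-averaged F1.

For archive mining, `mine_archive()` applies a fitted pipeline document by
document and emits an alert (with the selected evidence sentences) whenever
the prediction is a positive class; fallback predictions are never alerted.
The alerts are meant for expert confirmation, which is a human step outside
the package.

## The oracle test

Before training anything, `oracle_test()` bounds what a keyword list can
achieve: assign every keyword-containing document its gold label and every
keyword-free document the fallback label, then score micro-F1. The oracle
errs exactly on keyword-free positive documents (a keyword-bearing negative
still receives its gold negative label under this rule), so the score is the
ceiling for any classifier restricted to selected text. A score of 1 means
selection is lossless on that corpus.

## Micro-averaged F1

All evaluation uses micro-averaged F1: per-class true positives, false
positives and false negatives are pooled over classes before
`2·TP / (2·TP + FP + FN)`. In single-label multiclass prediction every error
is simultaneously one FP and one FN, so micro-F1 equals accuracy; the test
suite asserts this equivalence against an independent brute-force tally.

## TF-IDF keyword derivation

`extract_tfidf_keywords()` implements the unsupervised alternative to
guideline keywords: tokenize (English: whitespace tokens; Chinese: character
unigrams and bigrams — deliberately segmenter-free), weight by TF-IDF, take
the top 2000 candidates by maximum weight, drop terms containing digits,
punctuation, or characters outside the corpus's primary script, then score
each survivor by its mean TF-IDF weight in positive documents minus its mean
weight in fallback documents and keep positive scores. Two choices here were
genuinely open:

* **The TF-IDF variant.** We use raw term counts times the smoothed inverse
  document frequency `log((1 + n) / (1 + df)) + 1` with L2-normalized
  document vectors — the default of the most widely used vectorizer
  implementations, hence what a practitioner reproducing this kind of
  pipeline would get.
* **"Score higher than zero".** A raw TF-IDF weight is positive for every
  observed term, so thresholding it at zero would keep everything. The
  package reads the score as *discriminative*: positive-class mean weight
  minus fallback-class mean weight. This is the simplest reading under which
  a zero threshold meaningfully shrinks ~2000 candidates to a short feature
  list, and it provably ranks a marker term that occurs in all positives and
  no negatives at the top (a property the tests exercise).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `max_tokens` | 512 | the input window of standard contextual encoders; Longformer-class models are expressed as `truncate_encoder` with 4096 |
| `dim` | 256 | hashed n-gram bucket count / vector width; enough buckets that distinct marker vocabularies rarely collide, small enough for fast SVM training |
| `folds` | 10 | conventional CV depth; automatically reduced (with a warning) when the smallest class has fewer members |
| svc grid | C ∈ {0.1, 1, 10, 100} × kernel ∈ {linear, rbf} | standard small libsvm grid |
| sgd grid | loss ∈ {hinge, log} × α ∈ {1e-5 … 1e-1} | hinge ≈ linear SVM, log ≈ logistic regression; α is the L2 regularization strength |
| `test_fraction` | user-set | stratified with largest-remainder rounding so small classes keep printed-table-like proportions |

Sentence segmentation is rule-based: terminal punctuation (。！？； for
Chinese, `. ! ? ;` for English) plus newlines, with semicolons treated as
boundaries in both languages because clinical notes chain findings with
semicolons and keyword evidence stays local to the clause. No statistical
sentence-boundary model and no abbreviation dictionary are used; this is a
declared convention, and re-splitting any produced sentence returns the
sentence itself (idempotence), which selection relies on.

Length accounting follows each task's published convention: words
(whitespace-delimited) for English, non-whitespace characters for Chinese;
reported means are rounded half-up to integers.

## The synthetic corpus generator

Real corpora of this kind are private (hospital EHR data) or access-restricted
(the smoking challenge), so the package ships a seeded generator,
`generate_corpus()`, whose defaults encode the study conditions the pipeline
assumes:

* the five-class DHR scheme at its published training-set sizes
  (SJS 56, DIHS 44, AS 18, EB 32, NEG 323 — about 2:1 negative:positive);
* log-normal background lengths with mean ≈ 4000 Chinese characters and
  `sdlog = 0.65`, giving the heavy upper tail (maxima around 20,000
  characters) characteristic of concatenated inpatient notes;
* background sentences drawn from a boilerplate bank that is *screened at
  config time to contain no active keyword*, so separability is exact by
  construction;
* each positive document receives 1–3 label-specific marker sentences (each
  containing guideline keywords) with probability `keyword_injection_prob`
  (default 1); fallback documents receive a stray marker with probability
  `leakage_prob` (default 0).

With the defaults the oracle is exactly 1 on every seed; with injection
probability p < 1, oracle errors are Binomial(n_positives, 1 − p), and the
acceptance tests check the observed error count against the central 99%
binomial interval rather than a point value. `generate_archive()` produces an
unlabeled stream plus a withheld truth table for scoring mining
precision/recall.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: clinically realistic language and synonym
variation, keyword mentions in negated or historical contexts ("无过敏史"),
misspellings and formatting noise, patient-level longitudinal structure, and
markers that correlate with but do not determine the label. On real notes the
oracle is below 1 and classification is far harder; the synthetic results
validate the machinery (selection, embedding geometry, model selection,
mining bookkeeping), not clinical accuracy.

## Numerical and degenerate-input choices

* **Hashing.** Character n-grams (n = 1..3) are hashed by a base-31
  polynomial over Unicode code points plus a fixed offset, modulo `dim`; the
  hash seed is a package constant, so vectors are bit-reproducible across
  sessions. Empty text embeds to the zero vector (exempt from L2
  normalization).
* **Empty selections** flow through embedding and classification rather than
  being short-circuited to the fallback label; the classifier learns the
  empty-evidence → fallback mapping, keeping the training and inference
  paths identical.
* **SGD.** Minibatch (32) subgradient descent with learning rate
  `1 / (α·t + 1)` and iterate averaging over the last half of the epochs
  (30); averaging makes the optimum stable across the five-decade α grid.
* **Ties.** Grid-search ties break by grid order; prediction argmax ties
  break by class order; both are deterministic.
* **Seeds.** Every stochastic operation (splitting, generation, fold
  assignment, SGD shuffling) takes an explicit seed and restores the
  caller's RNG state, so a fixed seed implies identical output and seeded
  calls do not perturb the session RNG stream.
* A class with fewer than 2 members cannot be stratified and is an error; a
  training set with one class is an error for both keyword derivation and
  model fitting.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use the generator defaults
(473 documents, mean ≈ 4000 characters) for the end-to-end checks — oracle
exactness, held-out recovery of the selected-text pipeline versus the
original-text baseline, the length-reduction ratio, and archive mining over
200 documents at a 10% positive rate — and smaller explicit configurations
(mean 300 characters) for per-module unit tests. A full acceptance run takes
well under a minute of CPU.

## Limitations

* Keyword matching is surface-level: no negation handling, no synonym or
  terminology-ontology expansion, no stemming. A note mentioning a keyword
  in an irrelevant context is still selected; a paraphrase is missed.
* The bundled guideline list is task-specific; transferring the pipeline to
  a new phenotype requires a new keyword list (hand-picked or TF-IDF
  derived) and labeled training documents.
* Pretrained encoder backends are consumed, not provided; without one, the
  hashed n-gram backend carries all tests but does not model word meaning.
* Real-archive deployment needs site-specific preprocessing against badly
  formatted documents; `mine_archive()`'s lenient mode skips malformed
  records but cannot repair them.
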