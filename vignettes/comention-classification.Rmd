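---
title: "Classifying protein–phenotype co-mentions with self-training and a CNN/RNN ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying protein-phenotype co-mentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comention)
```

## The problem

A *co-mention* is a sentence in which a human protein (a UniProt entry) and
a Human Phenotype Ontology (HPO) term occur together. Co-occurrence alone is
weak evidence: "KIF4 was studied alongside cancer cell lines" co-mentions a
protein and a phenotype without asserting any biological relationship.
Biocurators who extend HPO annotations need the sentences that *do* assert a
relationship ("mutations in BRCA2 are associated with breast cancer risk"),
ranked so the best evidence surfaces first. `comention` implements the full
pipeline: dictionary-based co-mention extraction from a corpus, sentence
encoding, a semi-supervised classifier of *good* (label 1, valid
relationship) versus *bad* (label 0) co-mentions, an evaluation harness, and
a confidence-ranked retrieval engine.

The central difficulty is label scarcity: curated gold datasets in this
domain hold on the order of 1,500–2,000 sentences, while millions of
unlabeled co-mentions are cheap to extract. The package therefore combines
three ideas:

1. **Supervised base model** — fitted on the small labeled training split.
2. **Self-training** — the base model pseudo-labels a large unlabeled pool;
   a *validation-tuned number* of high-confidence predictions is added to
   the training set.
3. **Ensemble** — a convolutional and a recurrent text classifier are
   trained on the expanded set and their class-probability vectors averaged;
   the averaged positive-class probability is the *confidence score* used
   for ranking.

## Pipeline anatomy

### Extraction

Documents are split by a rule-based segmenter (terminal `.?!` followed by
whitespace and an uppercase letter or digit, with an abbreviation list; the
segmenter is an argument of `extract_comentions()` so a statistical one can
be swapped in). Entity matching is dictionary-based: case-insensitive,
anchored at token boundaries (so "AML" never fires inside "AML1"),
leftmost-longest, non-overlapping; protein and phenotype lexicons are
matched jointly so an overlap between the two kinds keeps the longer match.
A sentence with $m$ distinct proteins and $n$ distinct phenotypes yields
$m \times n$ records (one per id pair, spans at the first mention), because
gold labels in this domain are per sentence–pair. Statistical NER is
deliberately out of scope — recognition quality is an upstream concern.

### Preprocessing

Every lexicon match — not just the focal pair — is replaced by a sentinel
(`PROT` / `PHENO`). A consequence worth knowing: when several proteins
co-occur, the classifier cannot tell which pair is in focus. That mirrors
the stated procedure of the method this package implements, and its
published false-positive analysis shows exactly this failure mode. Tokens
are lowercased (sentinels excepted) and split on non-alphanumeric runs;
the vocabulary is built **from the training split only** (ids: 0 pad, 1
unknown, 2–3 sentinels, then tokens by descending frequency with
lexicographic tie-break); sequences are truncated/right-padded to `max_len`
(default 128 tokens, comfortably above biomedical sentence lengths).

The labeled set is split 60/20/20 (train/validation/test) by per-class
stratified sampling, rounding half up for test and validation and giving
the remainder to train. The reference gold dataset in this domain reports
1685 records split 1010/337/337 — those printed sizes sum to 1684; the
discrepancy is unexplained in the source and we do not force-match it.

### Models

All classifiers satisfy one contract: `train_classifier()` +
`predict_proba()` returning per-example two-class probability vectors
(rows sum to 1; fitting is deterministic given `cfg$seed`).

* **CNN** — embeddings trained from scratch (dim 100), parallel convolution
  widths {3,4,5} with 100 feature maps each, ReLU, global max-pooling,
  dense softmax.
* **RNN** — same embedding, single bidirectional recurrent layer (hidden
  128 per direction), final-state concatenation, dense softmax. The cell is
  a **GRU**: during development a vanilla tanh recurrence lost the
  mid-sentence relational cue long before the final state (held-out F1
  ≈ 0.78 versus ≈ 0.90 for the CNN on the synthetic world, degrading with
  further epochs — i.e. memorizing filler tokens), which is precisely the
  vanishing-signal problem gated cells exist to solve. Both networks train
  with Adam on binary cross-entropy for 20 epochs (batch 32, lr 1e-3,
  gradient-norm clip 5, optional decoupled weight decay); epochs, loss and
  optimizer follow the published setup, batch size and learning rate are
  unstated there and declared here. The implementation is plain R matrix
  code — the evaluation image offers no deep-learning framework — and every
  gradient path is verified against central finite differences in
  development.
* **lightweight** — ridge-penalized logistic regression (glmnet) over token
  counts. It exists so the whole pipeline is testable in seconds; it is a
  fixture, not a scientific claim.
* **base** — a plug-in point for a pretrained transformer
  (`train_config(base_factory = )`, fine-tuned `epochs_base = 4`). No
  pretrained weights ship with or are required by the package; when no
  factory is configured, `kind = "base"` errors and the lightweight model
  stands in as the self-training base.

`ensemble_predict()` averages member probability vectors with equal
weights; `predicted_class` is the argmax with exact ties going to class 0
(a tie does not assert a relation). The confidence score is the averaged
positive-class probability — the positive class, not the predicted class,
because ranking targets valid relationships.

### Self-training

`run_pipeline()` fits the base model, scores the pool, selects `k`
pseudo-labels, and trains the ensemble on the expanded set. "Top
predictions" is operationalized as *threshold-then-random-sample*: a pool
example is a candidate when its predicted-class probability is at least
`confidence_threshold` (default 0.9), and `k` candidates are drawn
uniformly at random (seeded). Both classes are added; by default per-class
quotas preserve the labeled training ratio (round half up for positives) to
avoid class drift, and a shortfall in one class is *not* backfilled from
the other (it is logged). `choose_added_size()` tunes `k` over candidate
sizes {1000, 2000, 3000, 5000, 10000} by mean validation F1 across seeded
repeats, ties to the smallest `k`; 5000 is the published default.
Self-training runs a single round: the base model is fitted once and only
the downstream ensemble is retrained per candidate `k`. Validation and test
sets are never pseudo-labeled; the pipeline enforces disjointness by record
identity and errors on overlap.

### Evaluation

Precision, recall and F1 use the standard confusion-matrix formulas with
zero denominators defined as 0. AUROC is the Mann–Whitney rank statistic
(ties ½) — exact under ties and equal to trapezoidal ROC integration.
`repeated_holdout()` reuses one fixed partition and varies only model
seeds (default 10 repeats), reporting per-repeat metrics, the mean, and a
population-denominator SD. `paired_ttest()` compares two models on
seed-aligned per-repeat F1 (configurable to another metric); degenerate
cases are conventions, not errors: all-zero differences give p = 1,
zero-variance nonzero differences give p = 0.

### Ranking

`score_store()` attaches ensemble confidences to a co-mention table and
indexes it; `query_rank()` filters by protein, phenotype or pair and sorts
by (confidence desc, doc_id asc, sentence_index asc) — the last two keys
exist only to make the order total and reproducible. Name→id resolution is
exact and case-insensitive; ambiguity is an error listing candidates.

## The synthetic world

`generate_dataset()` emits labeled/unlabeled/test co-mention records and a
corpus containing their sentences, from one generative story:

* Entity names are 1–3 unique six-letter consonant–vowel pseudowords; equal
  word length and global word uniqueness guarantee no name is a substring
  of another, and the strict CVCVCV pattern cannot collide with template
  English or the sentinels — so the extraction oracle is unambiguous.
* Each sentence embeds exactly one protein and one phenotype into a
  template plus filler words (target length 8–18 words). True positives
  carry a *relational* template ("mutations in P cause H", …) with
  probability `signal_strength` (default 0.9), otherwise an ambiguous
  co-occurrence template; negatives always use co-occurrence templates
  ("the panel included P as well as H", …). Ambiguous positives are thus
  distributionally identical to negatives, so the Bayes-optimal rule and
  its error are known by construction, and a large unlabeled pool carries
  exactly the signal a small labeled set under-samples — the situation
  self-training exploits.
* Observed labels flip with probability `label_noise` (default 0.05);
  per-subset positive counts are exact (`round_half_up(0.5 · n)`) before
  noise. Defaults — 100 labeled, 5000 unlabeled, 500 test — restate the
  small-gold-set / large-pool regime of the real task at desk scale.
* True generative labels travel in a separate `truth` component (written by
  the CLI to a `*_sidecar.tsv`); pipeline code never reads it, tests do.

What a green synthetic test does **not** establish: performance on real
biomedical language (negation, hedging, anaphora, misspelled entities,
imperfect NER), or the published headline numbers — those require the
deposited gold data, the ProPheno pool and a fine-tuned transformer, none
of which are available offline. The synthetic claims are *relative*
(self-training gain, ensemble ≥ members, ranking precision), which is what
the desk-scale acceptance criteria assert.

## Numerical and design notes

* All randomness descends from one seed through
  `derive_seed(seed, stage_name)`, so stages rerun independently and a
  `k = 0` self-training run is bit-identical to a supervised-only run.
* Stratified-split rounding: round half up per class for test/validation,
  remainder to train; classes with fewer than 3 records error.
* Probability ties at 0.5 predict class 0 everywhere.
* The vocabulary's frequency/lexicographic ordering uses C-locale radix
  sorting for cross-platform determinism.
* Spans are 0-based half-open character intervals over the sentence;
  co-mention TSVs serialize absent fields as empty strings and confidences
  at nine decimals.
* Known limitations: sentence-level only (a known 10–15% of valid relations
  cross sentence boundaries); dictionary matching misses unlisted surface
  forms; masking all entities erases focal-pair identity in multi-entity
  sentences.

## Reproducing the analysis scaffolding

```{r, eval = FALSE}
ds <- generate_dataset(synth_config(seed = 1))
pre <- preprocess_config(max_len = 32)
train <- encode_records(ds$labeled, ds$proteins, ds$phenotypes, cfg = pre)
pool <- encode_records(ds$unlabeled, ds$proteins, ds$phenotypes,
                       vocab = train$vocab, cfg = pre)
test <- encode_records(ds$test, ds$proteins, ds$phenotypes,
                       vocab = train$vocab, cfg = pre)
sp <- stratified_split(ds$labeled, split_config(seed = 1))
keys <- comention_keys(ds$labeled)
res <- run_pipeline(
  encoded_subset(train, keys %in% comention_keys(sp$train)),
  encoded_subset(train, keys %in% comention_keys(sp$validation)),
  pool, k = 2000, cfg = selftrain_config(seed = 1),
  tcfg = train_config(seed = 1))
pred <- ensemble_predict(res$ensemble, test)
compute_metrics(test$label, pred$predicted_class)
```
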