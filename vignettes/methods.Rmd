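---
title: "Methods: cascaded bleeding-event detection and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded bleeding-event detection and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bleedr` reimplements a clinical-NLP study design: detecting bleeding
adverse events in French hospital discharge summaries and grading their
severity, with two competing classifiers evaluated head-to-head — a
three-stage supervised sentence cascade and a rule-based classifier over
the stay's ICD-10 billing codes. Because the original annotated corpus is
confidential, the package ships a calibrated synthetic-corpus generator
that reproduces the corpus's statistical structure, so every component is
exercisable and testable end to end.

## The label scheme

Every sentence carries exactly one gold label from

* `IRRELEVANT` — no current bleeding event,
* `ANTECEDENT` — a historical bleeding mention (past episode, not the
  current stay),
* `CLIN_SIG` — a clinically significant current bleeding event,
* `SEVERE` — a current bleeding event meeting ISTH major-bleeding
  criteria (transfusion of red-cell units, a haemoglobin drop, or
  bleeding at a critical site such as intracranial/intraspinal).

A document's label set is the union of the non-`IRRELEVANT` labels of its
sentences (`aggregate_document()`); a document whose sentences are all
irrelevant has the empty label set. Documents are therefore multilabel,
sentences are not.

## The NLP cascade

Sentences are segmented (`segment_text()`, punctuation-based with an
abbreviation guard; fragments under three characters are dropped),
lowercased, tokenized on letter/digit runs, and encoded as sparse
bag-of-words counts over a vocabulary built from the training split only.

The cascade routes each sentence through up to three binary decisions,
all thresholded at score 0:

1. **Stage 1 — relevance filter.** L2-regularized (ridge) logistic
   regression, relevant vs irrelevant. Fitted with `glmnet`
   (`alpha = 0`); the search parameter `C` maps to
   `lambda = 1/(n * C)`. Balanced class weights
   `w(c) = N / (k * n_c)` enter as observation weights, countering the
   ~97.5% irrelevant majority.
2. **Stage 2 — relevant-sentence typing.** One-vs-rest linear SVMs
   (`e1071`, linear kernel, no rescaling) over `IRRELEVANT`,
   `ANTECEDENT`, and `BLEEDING` (the merged `CLIN_SIG`/`SEVERE` mass).
   The predicted class is the argmax of the three decision scores, ties
   broken by the fixed priority `IRRELEVANT < ANTECEDENT < BLEEDING`.
   Its training pool is the gold-positive sentences plus stage 1's
   out-of-fold false positives, so stage 2 learns to repair the
   filter's mistakes. All three one-vs-rest machines are always kept;
   a class absent from the pool gets a constant score of −1.
3. **Stage 3 — severity grading.** Ridge logistic regression,
   `CLIN_SIG` vs `SEVERE`, applied only to sentences stage 2 routed to
   `BLEEDING`.

Each stage's `C` is selected by 5-fold stratified cross-validation over
the grid {0.01, 0.1, 1, 10, 100}, maximizing the mean CV F1 of the
positive (stage 1/3) or rarest (stage 2) class. All randomness flows
through an explicit seed via an internal RNG-state-preserving wrapper, so
training is bit-reproducible. Trained models serialize to plain CSV/YAML
archives (`save_cascade()` / `load_cascade()`) with a manifest recording
the configuration, seed, and input checksums.

## The rule-based comparator

`classify_stay()` matches a stay's normalized ICD-10 codes (uppercased,
dots stripped) against two mutually exclusive code groups — clinically
significant vs severe bleeding — by prefix (so a category-level entry
like `R31` captures `R31.8`) or exact match. The arm emits any subset of
{`CLIN_SIG`, `SEVERE`}; it is structurally unable to produce
`ANTECEDENT`, so rule-arm evaluation excludes that class from scoring and
reports it as excluded. The bundled code table
(`inst/extdata/icd_bleeding_codes.csv`) is replaceable via
`load_code_table()`.

## Evaluation

`metrics_report()` computes one-vs-rest confusion counts per class and
from them accuracy, precision, recall, specificity, and F1, at sentence
or document granularity (document-level confusion treats the multilabel
sets by per-class membership, `IRRELEVANT` meaning the empty set). Macro
averages are unweighted class means; micro metrics pool the confusion
counts. Ratios with zero denominators are reported as 0 with an explicit
flag rather than `NaN`. Values are kept unrounded; `round_half_away()`
provides the half-away-from-zero rounding used for display. ROC curves
come from a full threshold sweep with trapezoidal AUC (equal to the
Mann–Whitney concordance with ties counted ½, which the tests verify),
and inter-method/inter-rater agreement uses hand-implemented Cohen and
Fleiss kappa, cross-checked in the test suite against `e1071` and `pROC`.

## The synthetic generator

`generate_corpus()` draws documents hierarchically:

1. With probability `p_irr = 0.3679` the document is irrelevant.
   Otherwise a latent label subset of {`ANTECEDENT`, `CLIN_SIG`,
   `SEVERE`} is drawn from independent Bernoullis, rejecting the empty
   set. The Bernoulli rates are calibrated so the *post-rejection*
   document marginals match the configured ones (defaults: 23.93%,
   50.36%, 27.50%).
2. Each of the document's `n` sentences (default uniform 120–210,
   matching the reference scale of ~65,700 sentences over 400
   documents) carries a latent label `l` with rate
   `r_l = prevalence_l / d_l`, where `d_l` is the exact post-rejection
   document marginal. Realized sentence prevalences therefore match the
   configured ones (defaults 97.45 / 0.33 / 1.91 / 0.32 %) exactly in
   expectation. Configurations with `r_l > 1` or rates summing past 1
   are rejected as infeasible.
3. Sentence text is filled from a template bank; the document's gold
   label set is re-derived as the union of realized sentence labels, so
   gold is consistent by construction. (A latent document label can
   fail to realize any sentence, so realized document marginals sit
   slightly below the latent targets — a known, documented bias.)
4. ICD codes are emitted per document: a matching group code with the
   configured sensitivity (defaults `CLIN_SIG` 0.77, `SEVERE` 0.03 —
   severe codes are rarely recorded, which is precisely the failure
   mode that motivates the NLP arm), plus non-bleeding noise codes and
   a small false-positive emission rate (0.05).

Three template banks set the difficulty: `"realistic"` (French clinical
fragments with shared vocabulary and negated bleeding mentions in the
irrelevant pool), `"separable"` (disjoint content words per label — a
positive control the cascade must recover), and `"none"` (one shared
generic pool — a negative control with no learnable signal). Generation
is deterministic down to bytes for a fixed configuration.

## Numerical and design choices worth knowing

* All decision thresholds sit at raw score 0; no post-hoc threshold
  tuning is performed anywhere.
* Stage-2 SVMs are stored as plain weight vectors
  (`w = t(SV) %*% coefs`, `b = -rho`, sign normalized), so archived and
  in-memory models score identically.
* The negative control is run at 20–40 sentences per document (document
  count and split unchanged): with no signal, stage 1's false positives
  flood the stage-2 SVM pool and full-length documents make libsvm
  training intractable. This is a problem-size choice for the control
  only; it does not alter generator probabilities or model settings.
* Fixture corpora in the unit tests use 30–60 sentences per document —
  at the default prevalences, shorter documents realize too few
  `SEVERE`/`ANTECEDENT` examples to train on.

## Limitations

The generator reproduces label *statistics*, not clinical language:
template-filled sentences are far easier than real discharge summaries,
so absolute cascade scores on synthetic corpora overstate what the
method achieves on real text. The bundled reference tables are inputs
for arithmetic checks, not recomputable outputs. The default ICD table
extends a handful of named codes with standard ICD-10 bleeding codes; a
production deployment should supply its own validated table.
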