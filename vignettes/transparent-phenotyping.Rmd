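---
title: "Transparent phenotyping from coded health records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transparent phenotyping from coded health records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhenoMiner)
```

## The model

PhenoMiner treats disease phenotyping as text categorisation. A patient's
coded record is a document; the exact ordering and dating of events is
discarded and only the number of occurrences of each clinical code is kept
(a bag of words). The cohort is then a sparse count matrix with codes as
rows and patients as columns, held as a `SummarizedExperiment` subclass with
the binary gold-standard outcome in `colData`. Working directly on raw codes
— rather than on latent embeddings — is a deliberate restriction: every
downstream object (a ranked code list, a tree split, an exported rule) stays
expressed in the vocabulary clinicians use, so the final phenotype
definition can be audited line by line.

The pipeline has three phases:

1. **Representation and splitting.** Counts, not presence flags, are stored;
   the tree engine exploits count thresholds (e.g. "more than one
   prescription"). Patients are split 60/20/20 into train/validation/test,
   stratified by outcome. Stratification is the package's choice: at 2%
   prevalence an unstratified 20% part can easily contain almost no
   positives, making validation accuracy uninformative. The vocabulary is by
   default built from the full cohort before splitting (mirroring the usual
   practice of fixing the term space first); a training-only vocabulary can
   be passed explicitly where leakage through the term space is a concern —
   note that code *identity* carries no outcome information by itself, so
   the risk is second order.
2. **Ranking and forward selection.**
3. **Tree tuning and final selection.**

## The five ranking indices

All five indices operate on the same 2×2 table per code: `A`/`B` positives
and negatives carrying the code (presence = count ≥ 1), `C`/`D` those
without it. Binarization here is a documented choice: the indices are
2×2-table statistics, while the raw counts remain available to the trees.
The indices are:

* **χ²**: `N(AD−BC)² / ((A+B)(C+D)(A+C)(B+D))`.
* **Gini gain, information gain, DKM gain**: all impurity gains
  `imp(parent) − Σ (n_child/N)·imp(child)` with impurity `2q(1−q)`, Shannon
  entropy (base 2; ranking is base-invariant), and `2√(q(1−q))`
  respectively, where `q` is the positive-class proportion.
* **Binomial enrichment**: `−log10 P(X ≥ A)` with
  `X ~ Binomial(A+B, (A+C)/N)` — how surprising the code's concentration in
  positives is under the class-prevalence null. This exact one-sided tail is
  the standard term-enrichment form used in text categorisation; it is an
  interpretation, as the index is known under several variants.

Codes present in every patient or in none score 0 under every index: they
cannot discriminate. The Gini gain satisfies the algebraic identity
`giniGain = chi2Score · Gini(parent) / N`, so χ² and Gini always produce the
same ranking — the package's test-suite verifies the identity to 1e-12 on
random tables, and the ranking code sorts on a 10-significant-digit key so
that mathematically tied scores computed through different floating-point
routes still tie exactly (falling back to lexicographic code order, which
keeps every ranking fully deterministic).

## Forward selection

Given a ranked list Ω, the candidate set grows by one code per step:
Σ\_i = Σ\_{i−1} ∪ Ω(i). At each step a classifier is fitted on the training
part restricted to Σ\_i and scored on the validation part; the sweep exits
early when the validation error reaches a tolerance (default 0, i.e. only a
perfect validation split stops it early) and otherwise runs to `i_max`
(default 400, clipped to the vocabulary). The best and second-best steps by
(accuracy, F1), ties towards fewer features, both go to the tuning phase so
that a near-tied, slightly larger subset is not lost. Parsimony as the tie
break is the package's choice: reported optima frequently tie to the printed
precision, and the smaller feature set is the more transparent one.

The default step-2 learner is an entropy-criterion tree with no cost
weighting (`min_split` 20, `min_child` 7 — rpart-like defaults); it is
injectable, since the procedure is learner-agnostic. The sweep costs at most
`i_max` fits against `K(K+1)/2` for exhaustive wrapper selection; the
returned trace records the fit count and the tests assert the bound.

## The tree engine

The decision-tree engine is written from scratch so that its behaviour is
fully specified here, rather than delegated to an external implementation:

* **Splits** are binary on count thresholds, candidates at midpoints
  between adjacent observed values. Equal-gain ties resolve to the lowest
  feature column, then the smallest threshold — fits are deterministic.
* **Cost sensitivity**: each positive patient carries weight `fn_cost`
  (false-positive cost fixed at 1) in every count, impurity and leaf label.
  A leaf predicts positive when `fn_cost·n_pos ≥ n_neg` — the
  expected-cost-minimizing label, ties to the positive class so that a
  maximally ambiguous leaf errs on the side of case finding.
* **Stopping**: pure node, node smaller than `min_split`, no split leaving
  both children ≥ `min_child`, or non-positive gain.
* **Profiles**: `cart` (Gini criterion plus cost-complexity pruning at
  `cp`: repeatedly collapse the internal node with the smallest risk saved
  per extra leaf relative to root risk, while below `cp`); `c50` (entropy
  criterion, `min_child` and `fn_cost` as the tuned levers — an
  approximation of C5.0's behaviour without winnowing, boosting or rule
  post-simplification, which are proprietary internals); `ci` (the chosen
  split must pass a χ² association test with Bonferroni correction over the
  candidate features at level `1 − mincriterion` — an approximation of
  conditional-inference stopping without the permutation-test machinery).
  The conditional-inference "minimum sum of weights" lever maps onto
  `min_split`; exact semantics of the original differ and no numerical
  replication of rpart/C5.0/party output is attempted.
* **Rules**: each leaf exports the conjunction of its path literals with
  training support and confidence; rules are mutually exclusive and
  exhaustive, and a code dictionary can annotate them with descriptions.

Missing values cannot occur: a code that was never recorded has count 0 by
construction, so there are no surrogate splits.

## Tuning and evaluation

Grid search uses stratified k-fold cross-validation (default 10-fold, fixed
seed) and scores each grid point by the mean held-out overall agreement
rate — plain accuracy; the asymmetric cost shapes *fitting*, never the
selection metric, so that raising `fn_cost` expresses a preference through
the model rather than through the yardstick. Default axes follow the
regimes a practitioner would sweep for these tree families: c50 `min_child`
5–30 by 5 and `fn_cost` 1–20 by 1.25; cart `min_split` 10–40 by 5 and `cp`
0.001–0.1 by 0.001; ci `mincriterion` 0.1–0.9 by 0.1 plus 0.99 and
`min_split` 35–45 by 5. (The `fn_cost` axis read literally from "1 to 20 in
steps of 1.25" ends at 19.75.) Across candidate feature lists the final
model is the refit with the best validation accuracy (F1, then fewer
features as tie-breaks), reported once on the untouched test part.

All six metrics (accuracy, sensitivity, specificity, PPV, NPV, F1) report
`NA` — never 0 — when their denominator is empty; F1 is the harmonic mean
of precision and recall and is `NA` when both are zero (with any predicted
and any true positives present, either being zero forces the other to zero,
so the two conventions coincide). `reconstructConfusion()` inverts printed
sensitivity/specificity and split sizes back to integer confusion counts
with half-up rounding — confusion counts are integers — which is how the
package checks published performance tables for internal consistency.

## The synthetic-cohort generator

`generateCohort()` emulates the structure of a linked primary-care cohort:
outcome ~ Bernoulli(prevalence); events per patient ~ Poisson(mean_events);
event codes from a Zipf-weighted categorical (heavy-tailed background usage,
default exponent 1.2), with planted informative codes whose per-event
probability is `base_rate` in negatives and `rate_ratio · base_rate` in
positives. Multiplying the per-event weight (rather than a per-patient
presence probability) keeps the *count* structure informative, which is what
exercises the trees' count thresholds. Labels are drawn before events from a
single seeded stream, so cohorts are byte-reproducible and the caller's RNG
state is untouched.

What it deliberately does not model: longitudinal progression, correlation
between codes beyond the planted signal, code-hierarchy structure, and
coding-practice drift. Passing tests on these cohorts therefore demonstrate
correctness of the machinery and recoverability of planted signal — not
clinical performance on real records.

Benchmark fixtures: `tiny_separable` (12 patients, one code identical to
the outcome), `tiny_imbalanced` (50 patients, 2 positives whose only
informative code is shared with 8 negatives — the smallest cohort where the
cost lever visibly flips a leaf), `as_like` (2000 patients, 2% prevalence,
two planted codes at rate ratio 8, named `N100.` and `F440.` after the
classic spondyloarthritis/uveitis pair) and `ra_like` (2000 patients, 14%
prevalence, ten planted codes). The tiny pair ship as CSVs; the large two
are regenerated from fixed seeds at call time, keeping the repository free
of bulk data.

## Numerical choices and problem sizes

* Entropy uses the `0·log 0 = 0` convention; all gains are clamped at 0.
* Gains must exceed 1e-12 to count as positive (guards against
  floating-point ghosts creating spurious splits).
* The binomial tail is computed on the log scale (`pbinom(..., log.p)`), so
  scores stay finite and ordered even for extremely enriched codes.
* Stratified splitting uses largest-remainder apportionment per class, so
  every part's class size is within one patient of its target fraction.
* Validation studies in the test-suite and acceptance script use cohorts of
  n = 2000 with 500 codes, 20 seeds, and forward-selection sweeps to
  i\_max = 30 — sizes at which every statistic of interest is stable while
  a full run stays comfortably interactive. The null-calibration check
  (no planted signal ⇒ no code clears a Bonferroni χ² bar) runs at n = 1000
  with 50 codes and 20 events per patient so that even the rarest code has
  dozens of carriers: the χ² reference is asymptotic, and in a sparser
  regime its nominal level simply does not apply.

## Known limitations

* No code-hierarchy expansion: codes are opaque tokens, so a phenotype
  spread thinly across many sibling codes will rank lower than its true
  signal. This is the price of transparency at the raw-code level.
* The ci profile's association gate uses the asymptotic χ² distribution;
  at very small node sizes its p-values are approximate.
* Forward selection is greedy over a fixed ranking: a code pair that is
  informative only jointly can be missed (no floating or backward search).
* Metrics tied to very few positives (e.g. PPV at 2% prevalence) have wide
  sampling variability; the package reports them but cannot stabilize them.
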