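# PhenoMiner

Transparent machine-learning phenotyping from coded electronic health
records (EHRs).

## The problem

Identifying every patient in a primary-care population who has a given
condition (e.g. rheumatoid arthritis or ankylosing spondylitis) is hard:
diagnostic codes in primary care are noisy, the coding vocabularies (Read,
SNOMED-CT) contain tens of thousands of overlapping terms, and true cases
are rare (often 2–15% prevalence). Black-box classifiers can predict the
label but cannot tell a clinician *why* — and for clinical decision support
and governance the *why* is the point.

PhenoMiner implements a fully transparent pipeline for this problem,
aimed at health-informatics researchers with a linked, gold-standard-labelled
cohort (or no data at all — a synthetic-cohort simulator is built in):

1. **Bag-of-words patient representation.** Each patient is a document of
   clinical codes; only occurrence counts matter. The cohort becomes a
   sparse codes × patients count matrix (`PatientTermMatrix`, a
   `SummarizedExperiment`), split 60/20/20 into stratified
   train/validation/test parts.
2. **Feature ranking.** Every code is scored against the outcome on its 2×2
   presence table (cells A, B, C, D) by five indices: the χ² statistic
   `N(AD−BC)²/((A+B)(C+D)(A+C)(B+D))`, Gini gain, information gain (bits),
   DKM gain (impurity `2√(q(1−q))`), and a −log10 exact binomial
   enrichment tail. χ² and Gini gain obey
   `giniGain = chi2 · Gini(parent)/N` exactly, so they always rank
   identically.
3. **Forward selection.** Codes enter in rank order, one at a time; a
   decision tree is refit at each size and scored on the validation split.
   This costs at most `i_max` fits instead of `K(K+1)/2` for exhaustive
   wrapper selection. The best and second-best cut-off points go forward.
4. **Cost-sensitive, rule-exporting trees.** A from-scratch decision-tree
   engine with three profiles (CART-like, C5.0-like, conditional-inference-
   like), asymmetric false-negative cost for the rare positive class,
   cost-complexity pruning, and grid search tuned by stratified 10-fold
   cross-validation. Every fitted tree exports its leaves as plain decision
   rules.

## Worked example

```r
library(PhenoMiner)

# a 2000-patient cohort, 2% prevalence, two planted codes at rate ratio 8
fx  <- goldenFixture("as_like")
ptm <- buildPatientTermMatrix(fx$events, fx$labels)
ptm
#> PatientTermMatrix: 500 codes x 2000 patients (42 positive, 2.10% prevalence)
#>   non-zero entries: 26638

plan <- splitPatients(ptm, seed = 7)
tr <- splitPart(ptm, plan, "train"); va <- splitPart(ptm, plan, "validation")

rk <- rankFeatures(ptm, "chi2", subset = patientIDs(tr))
head(rankingTable(rk), 2)
#>   rank  code     score
#> 1    1 F440. 102.40986
#> 2    2 N100.  45.11903

sel <- forwardSelect(rk, tr, va, i_max = 10)
sel
#> SelectionTrace (chi2): 10 steps, best cut-off 2, second 3, 10 fits

m <- fitTree(tr, topCodes(rk, 2), treeParams(profile = "c50", fn_cost = 5))
writeLines(head(exportRules(m)$text, 2))
#> IF F440. <= 1 AND N100. <= 1 AND F440. <= 0 THEN 0 (support=973, confidence=1.00)
#> IF F440. <= 1 AND N100. <= 1 AND F440. > 0 AND N100. <= 0 THEN 0 (support=127, confidence=0.98)

performance(confusionCounts(outcomeLabels(va), predict(m, va)))
#> PerformanceReport: TP=5 FP=5 FN=4 TN=387
#>   accuracy=0.9776 sensitivity=0.5556 specificity=0.9872
#>   ppv=0.5000 npv=0.9898 f1=0.5263
```

The two planted codes are recovered as the top-ranked pair, forward
selection stops the feature set at two codes, and the exported rules state
the resulting phenotype definition in clinical-code terms. `runPipeline()`
chains all stages from a YAML config and writes every artifact (matrix,
ranked lists, traces, grid tables, final model JSON, rules, report);
`inst/scripts/phenominer.R` wraps `simulate` and `run` for shell use.

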