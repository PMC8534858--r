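#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

#' Patient-term matrix with aligned outcome labels
#'
#' The bag-of-words representation of a coded-EHR cohort: a sparse
#' non-negative integer count matrix with clinical codes as rows and patients
#' as columns (the `"counts"` assay), plus the binary gold-standard outcome in
#' `colData(x)$outcome` (1 = has the condition). Entry `[j, i]` is the number
#' of event rows recorded for patient `i` with code `j`; event order and dates
#' play no role. Build one with [buildPatientTermMatrix()].
#'
#' @seealso [buildPatientTermMatrix()], [splitPatients()], [rankFeatures()]
#' @export
setClass("PatientTermMatrix", contains = "SummarizedExperiment")

setValidity("PatientTermMatrix", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts@x < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cts@x != floor(cts@x))) msg <- c(msg, "counts must be integral")
  }
  if (!"outcome" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'outcome' is required")
  else {
    y <- object$outcome
    if (!all(y %in% c(0L, 1L))) msg <- c(msg, "outcome must be binary 0/1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Codes ranked by an association index
#'
#' An ordered feature list: every vocabulary code scored by one of the
#' five association indices and sorted by decreasing score, ties broken
#' lexicographically by code. Produced by [rankFeatures()].
#'
#' @slot method one of `"chi2"`, `"gini"`, `"info_gain"`, `"dkm"`, `"binomial"`.
#' @slot ranking `data.frame` with columns `rank`, `code`, `score`.
#' @export
setClass("RankedFeatures",
         representation(method = "character", ranking = "data.frame"))

setValidity("RankedFeatures", function(object) {
  msg <- NULL
  ok <- c("chi2", "gini", "info_gain", "dkm", "binomial")
  if (length(object@method) != 1L || !object@method %in% ok)
    msg <- c(msg, sprintf("method must be one of %s", paste(ok, collapse = ", ")))
  r <- object@ranking
  if (!all(c("rank", "code", "score") %in% names(r)))
    msg <- c(msg, "ranking needs columns rank, code, score")
  else {
    if (nrow(r) && any(diff(r$score) > 1e-12))
      msg <- c(msg, "scores must be non-increasing")
    if (nrow(r) && any(r$score < -1e-12))
      msg <- c(msg, "scores must be non-negative")
    if (anyDuplicated(r$code)) msg <- c(msg, "codes must be unique")
  }
  if (is.null(msg)) TRUE else msg
})

#' Forward-selection trace
#'
#' Record of the rank-ordered forward-selection sweep: per feature-count `i`
#' the validation accuracy and F1 of a classifier trained on the top-`i`
#' ranked codes, the chosen best and second-best cut-off points, and the
#' number of classifier fits spent. Produced by [forwardSelect()].
#'
#' @slot method ranking method the swept list came from.
#' @slot steps `data.frame` with columns `i`, `accuracy_val`, `f1_val`.
#' @slot best_cutoff,second_cutoff selected feature counts (second may be
#'   `NA` when only one step was evaluated).
#' @slot tolerance validation-error tolerance used for early stopping.
#' @slot n_fits number of classifier fits performed (always `<= i_max`).
#' @export
setClass("SelectionTrace",
         representation(method = "character", steps = "data.frame",
                        best_cutoff = "integer", second_cutoff = "integer",
                        tolerance = "numeric", n_fits = "integer"))

setValidity("SelectionTrace", function(object) {
  msg <- NULL
  s <- object@steps
  if (!all(c("i", "accuracy_val", "f1_val") %in% names(s)))
    msg <- c(msg, "steps needs columns i, accuracy_val, f1_val")
  else if (nrow(s) && !identical(as.integer(s$i), seq_len(nrow(s))))
    msg <- c(msg, "steps must cover i = 1..i_max consecutively")
  if (!object@best_cutoff %in% s$i)
    msg <- c(msg, "best_cutoff must be an evaluated step")
  if (!is.na(object@second_cutoff) && !object@second_cutoff %in% s$i)
    msg <- c(msg, "second_cutoff must be an evaluated step")
  if (is.null(msg)) TRUE else msg
})

#' Decision-tree hyper-parameters
#'
#' Parameter bundle for [fitTree()]. `profile` selects the behavioural
#' profile: `"cart"` (Gini criterion, cost-complexity pruning via `cp`),
#' `"c50"` (entropy criterion, `min_child` and asymmetric `fn_cost` as the
#' tuned levers) or `"ci"` (splits gated by a Bonferroni-corrected chi-squared
#' association test at `mincriterion`). Construct with [treeParams()], which
#' validates ranges.
#'
#' @slot profile `"cart"`, `"c50"` or `"ci"`.
#' @slot criterion impurity used for split gain: `"gini"`, `"entropy"`, `"dkm"`.
#' @slot min_split smallest node size eligible for splitting.
#' @slot min_child smallest allowed child node.
#' @slot fn_cost cost of calling a true positive negative (false-positive
#'   cost fixed at 1); implemented by weighting positive patients.
#' @slot cp complexity parameter for pruning (cart profile).
#' @slot mincriterion 1 minus the p-value a split must beat (ci profile).
#' @slot seed integer seed (kept for provenance; fitting is deterministic).
#' @export
setClass("TreeParams",
         representation(profile = "character", criterion = "character",
                        min_split = "numeric", min_child = "numeric",
                        fn_cost = "numeric", cp = "numeric",
                        mincriterion = "numeric", seed = "integer"))

#' Fitted transparent decision tree
#'
#' A recursively grown, cost-aware binary decision tree over code-count
#' features. Nodes split as `count <= threshold` (left) versus
#' `count > threshold` (right); each leaf predicts the class with the lower
#' expected misclassification cost (ties go to the positive class). Fit with
#' [fitTree()]; convert to human-readable rules with [exportRules()].
#'
#' @slot root nested list of nodes (split, class counts, children).
#' @slot params the [TreeParams-class] used.
#' @slot features codes offered to the tree, in column order at fit time.
#' @export
setClass("PhenoTree",
         representation(root = "list", params = "TreeParams",
                        features = "character"))

#' Cross-validated grid-search result
#'
#' One row per grid point with its mean held-out agreement rate (plain
#' accuracy averaged over stratified folds), plus the winning parameter
#' combination. Produced by [crossValidatedGridSearch()].
#'
#' @slot profile tree profile searched.
#' @slot table `data.frame` of grid points and `cv_agreement`.
#' @slot best named list of the winning parameter values.
#' @slot n_fits number of tree fits performed (folds x grid points).
#' @export
setClass("GridResult",
         representation(profile = "character", table = "data.frame",
                        best = "list", n_fits = "integer"))

#' Confusion matrix and derived performance metrics
#'
#' Holds TP/FP/FN/TN counts and the six metrics used throughout:
#' accuracy, sensitivity (recall), specificity, PPV (precision), NPV and F1.
#' Ratios with a zero denominator are `NA`, never 0. Build from counts with
#' [performance()] or from predictions with [confusionCounts()].
#'
#' @slot confusion named numeric (`TP`, `FP`, `FN`, `TN`).
#' @slot metrics named numeric of the six metrics, proportions in \[0, 1\].
#' @export
setClass("PerformanceReport",
         representation(confusion = "numeric", metrics = "numeric"))

setValidity("PerformanceReport", function(object) {
  msg <- NULL
  if (!all(c("TP", "FP", "FN", "TN") %in% names(object@confusion)))
    msg <- c(msg, "confusion needs TP, FP, FN, TN")
  else if (any(object@confusion < 0)) msg <- c(msg, "counts must be >= 0")
  need <- c("accuracy", "sensitivity", "specificity", "ppv", "npv", "f1")
  if (!all(need %in% names(object@metrics)))
    msg <- c(msg, "metrics incomplete")
  if (is.null(msg)) TRUE else msg
})
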