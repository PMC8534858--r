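# Accessors and show() methods for the core classes.

#' Accessors for PatientTermMatrix
#'
#' `termCounts()` returns the sparse codes-by-patients count matrix,
#' `patientIDs()` the patient identifiers (columns), `codeIDs()` the
#' vocabulary (rows), and `outcomeLabels()` the aligned 0/1 outcome vector.
#'
#' @param x a [PatientTermMatrix-class].
#' @return see individual descriptions.
#' @export
termCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname termCounts
#' @export
patientIDs <- function(x) colnames(x)

#' @rdname termCounts
#' @export
codeIDs <- function(x) rownames(x)

#' @rdname termCounts
#' @export
outcomeLabels <- function(x) setNames(as.integer(x$outcome), colnames(x))

setMethod("show", "PatientTermMatrix", function(object) {
  y <- object$outcome
  cat(sprintf("PatientTermMatrix: %d codes x %d patients (%d positive, %.2f%% prevalence)\n",
              nrow(object), ncol(object), sum(y),
              if (ncol(object)) 100 * mean(y) else 0))
  cat(sprintf("  non-zero entries: %d\n",
              length(SummarizedExperiment::assay(object, "counts")@x)))
})

#' Accessors for RankedFeatures
#'
#' `rankingTable()` returns the rank/code/score data.frame;
#' `rankingMethod()` the index that produced it; `topCodes()` the first `n`
#' codes in rank order.
#'
#' @param x a [RankedFeatures-class].
#' @param n number of leading codes.
#' @export
rankingTable <- function(x) x@ranking

#' @rdname rankingTable
#' @export
rankingMethod <- function(x) x@method

#' @rdname rankingTable
#' @export
topCodes <- function(x, n) head(x@ranking$code, n)

setMethod("show", "RankedFeatures", function(object) {
  cat(sprintf("RankedFeatures (%s): %d codes\n", object@method, nrow(object@ranking)))
  print(head(object@ranking, 5))
  if (nrow(object@ranking) > 5) cat("  ...\n")
})

#' Accessors for SelectionTrace
#'
#' `selectionSteps()` returns the per-step validation metrics; `bestCutoff()`
#' and `secondCutoff()` the two retained cut-off points; `fitCount()` the
#' number of classifier fits spent by the sweep.
#'
#' @param x a [SelectionTrace-class].
#' @export
selectionSteps <- function(x) x@steps

#' @rdname selectionSteps
#' @export
bestCutoff <- function(x) x@best_cutoff

#' @rdname selectionSteps
#' @export
secondCutoff <- function(x) x@second_cutoff

#' @rdname selectionSteps
#' @export
fitCount <- function(x) x@n_fits

setMethod("show", "SelectionTrace", function(object) {
  cat(sprintf("SelectionTrace (%s): %d steps, best cut-off %d, second %s, %d fits\n",
              object@method, nrow(object@steps), object@best_cutoff,
              ifelse(is.na(object@second_cutoff), "NA", object@second_cutoff),
              object@n_fits))
})

setMethod("show", "TreeParams", function(object) {
  cat(sprintf("TreeParams: profile=%s criterion=%s min_split=%g min_child=%g fn_cost=%g cp=%g mincriterion=%g\n",
              object@profile, object@criterion, object@min_split,
              object@min_child, object@fn_cost, object@cp, object@mincriterion))
})

#' Tree size accessors
#'
#' `nodeCount()` counts all nodes, `leafCount()` the leaves of a fitted tree.
#'
#' @param x a [PhenoTree-class].
#' @export
nodeCount <- function(x) {
  count <- function(nd) if (is.null(nd$children)) 1L else
    1L + count(nd$children$left) + count(nd$children$right)
  count(x@root)
}

#' @rdname nodeCount
#' @export
leafCount <- function(x) (nodeCount(x) + 1L) %/% 2L

setMethod("show", "PhenoTree", function(object) {
  cat(sprintf("PhenoTree (%s, %s criterion): %d nodes, %d leaves, %d candidate features\n",
              object@params@profile, object@params@criterion,
              nodeCount(object), leafCount(object), length(object@features)))
})

#' Grid-search accessors
#'
#' `gridTable()` returns the per-point results, `bestParams()` the winning
#' parameter values, `gridFits()` the number of tree fits performed.
#'
#' @param x a [GridResult-class].
#' @export
gridTable <- function(x) x@table

#' @rdname gridTable
#' @export
bestParams <- function(x) x@best

#' @rdname gridTable
#' @export
gridFits <- function(x) x@n_fits

setMethod("show", "GridResult", function(object) {
  cat(sprintf("GridResult (%s): %d grid points, best cv agreement %.4f\n",
              object@profile, nrow(object@table), max(object@table$cv_agreement)))
  cat("  best:", paste(names(object@best), unlist(object@best),
                       sep = "=", collapse = " "), "\n")
})

#' Accessors for PerformanceReport
#'
#' `confusion()` returns the named TP/FP/FN/TN counts and `metrics()` the six
#' derived proportions.
#'
#' @param x a [PerformanceReport-class].
#' @export
confusion <- function(x) x@confusion

#' @rdname confusion
#' @export
metrics <- function(x) x@metrics

setMethod("show", "PerformanceReport", function(object) {
  cm <- object@confusion
  cat(sprintf("PerformanceReport: TP=%d FP=%d FN=%d TN=%d\n",
              cm["TP"], cm["FP"], cm["FN"], cm["TN"]))
  m <- object@metrics
  cat(sprintf("  accuracy=%.4f sensitivity=%.4f specificity=%.4f\n",
              m["accuracy"], m["sensitivity"], m["specificity"]))
  cat(sprintf("  ppv=%.4f npv=%.4f f1=%.4f\n", m["ppv"], m["npv"], m["f1"]))
})
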