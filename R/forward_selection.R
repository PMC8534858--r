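# Phase 2b: rank-ordered forward selection. The candidate feature set grows
# one ranked code at a time (nested growth); at each size a classifier is
# trained on the training view and scored on the validation view. This costs
# at most i_max classifier fits, against K(K+1)/2 for exhaustive forward
# selection over K features.

.valMetrics <- function(model, val) {
  pred <- predict(model, val)
  truth <- outcomeLabels(val)
  rep <- performance(confusionCounts(truth, pred))
  m <- metrics(rep)
  c(accuracy = unname(m["accuracy"]),
    f1 = unname(ifelse(is.na(m["f1"]), 0, m["f1"])))
}

#' Forward selection over a ranked feature list
#'
#' Starting from the empty set, adds the next-ranked code at each step, fits
#' the learner on the training view restricted to the current set and
#' evaluates accuracy and F1 on the validation view. Stops early once the
#' validation error `1 - accuracy` drops to `tolerance` or below, otherwise
#' sweeps to `i_max`. The best and second-best cut-offs are the steps with
#' the (second-)highest (accuracy, F1) pair, ties broken towards fewer
#' features.
#'
#' @param ranked a [RankedFeatures-class].
#' @param train,val disjoint [PatientTermMatrix-class] views.
#' @param learner classifier factory `function(train_view, features)`
#'   returning an object with a `predict` method; default fits an
#'   entropy-criterion tree with no cost weighting.
#' @param i_max largest feature count to evaluate (clipped to the vocabulary
#'   size with a warning); default 400.
#' @param tolerance validation-error threshold for the early exit; default 0
#'   (stops only on a perfect validation split).
#' @return a [SelectionTrace-class].
#' @export
forwardSelect <- function(ranked, train, val, learner = NULL,
                          i_max = 400L, tolerance = 0) {
  if (length(intersect(patientIDs(train), patientIDs(val))))
    pmStop("train and validation views share patients", "config_error")
  if (length(unique(outcomeLabels(train))) < 2L)
    pmStop("training view has a single class", "degenerate_label_error")
  if (i_max < 1L) pmStop("i_max must be >= 1", "config_error")
  if (is.null(learner))
    learner <- function(tr, feats)
      fitTree(tr, feats, treeParams(profile = "c50", fn_cost = 1))
  K <- nrow(rankingTable(ranked))
  if (i_max > K) {
    warning(sprintf("i_max %d exceeds vocabulary size %d; clipped", i_max, K))
    i_max <- K
  }
  codes <- rankingTable(ranked)$code
  steps <- data.frame(i = integer(), accuracy_val = numeric(),
                      f1_val = numeric())
  n_fits <- 0L
  for (i in seq_len(i_max)) {
    model <- learner(train, codes[seq_len(i)])
    n_fits <- n_fits + 1L
    m <- .valMetrics(model, val)
    steps <- rbind(steps, data.frame(i = i, accuracy_val = m["accuracy"],
                                     f1_val = m["f1"]))
    if (1 - m["accuracy"] <= tolerance) break
  }
  rownames(steps) <- NULL
  ord <- order(-steps$accuracy_val, -steps$f1_val, steps$i)
  best <- steps$i[ord[1L]]
  second <- if (length(ord) >= 2L) steps$i[ord[2L]] else NA_integer_
  new("SelectionTrace", method = rankingMethod(ranked), steps = steps,
      best_cutoff = as.integer(best), second_cutoff = as.integer(second),
      tolerance = as.numeric(tolerance), n_fits = n_fits)
}

#' Feature subsets carried to the tuning phase
#'
#' The top-ranked prefixes at the best and second-best cut-off points; the
#' two subsets are nested whenever the cut-offs differ.
#'
#' @param trace a [SelectionTrace-class].
#' @param ranked the [RankedFeatures-class] the trace was computed from.
#' @return list of one or two character vectors of codes (`best`, `second`).
#' @export
featureSubsets <- function(trace, ranked) {
  codes <- rankingTable(ranked)$code
  out <- list(best = codes[seq_len(bestCutoff(trace))])
  if (!is.na(secondCutoff(trace)))
    out$second <- codes[seq_len(secondCutoff(trace))]
  out
}
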