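# Phase 3 orchestration and performance accounting: stratified 10-fold
# grid search, final model selection across candidate feature lists, the six
# metrics, and confusion-matrix reconstruction from printed summary rates.

#' Confusion counts from truth and prediction vectors
#'
#' @param truth,pred aligned 0/1 vectors.
#' @return named numeric `c(TP, FP, FN, TN)`.
#' @export
confusionCounts <- function(truth, pred) {
  if (length(truth) != length(pred))
    pmStop("truth and prediction lengths differ", "config_error")
  c(TP = sum(truth == 1 & pred == 1), FP = sum(truth == 0 & pred == 1),
    FN = sum(truth == 1 & pred == 0), TN = sum(truth == 0 & pred == 0))
}

.safeRatio <- function(num, den) if (den > 0) num / den else NA_real_

#' Performance metrics from a confusion matrix
#'
#' Computes accuracy, sensitivity (recall), specificity, PPV (precision),
#' NPV and the F1-score (harmonic mean of precision and recall). Any ratio
#' with a zero denominator is `NA`, never 0; in particular F1 is `NA` when
#' precision and recall are both zero or undefined.
#'
#' @param cm named numeric `c(TP, FP, FN, TN)` (from [confusionCounts()] or
#'   [reconstructConfusion()]).
#' @return a [PerformanceReport-class].
#' @export
performance <- function(cm) {
  if (!all(c("TP", "FP", "FN", "TN") %in% names(cm)))
    pmStop("need named counts TP, FP, FN, TN", "config_error")
  if (any(cm < 0) || sum(cm) <= 0)
    pmStop("counts must be >= 0 with positive total", "config_error")
  TP <- cm[["TP"]]; FP <- cm[["FP"]]; FN <- cm[["FN"]]; TN <- cm[["TN"]]
  recall <- .safeRatio(TP, TP + FN)
  prec <- .safeRatio(TP, TP + FP)
  f1 <- if (is.na(recall) || is.na(prec) || (recall + prec) == 0) NA_real_
  else 2 * recall * prec / (recall + prec)
  new("PerformanceReport",
      confusion = c(TP = TP, FP = FP, FN = FN, TN = TN),
      metrics = c(accuracy = (TP + TN) / sum(cm),
                  sensitivity = recall,
                  specificity = .safeRatio(TN, TN + FP),
                  ppv = prec,
                  npv = .safeRatio(TN, TN + FN),
                  f1 = f1))
}

#' Reconstruct a confusion matrix from printed summary rates
#'
#' Given the positive/negative class sizes of an evaluation split and a
#' model's printed sensitivity and specificity, recovers the integer
#' confusion counts: `TP = round(sensitivity * n_pos)` and
#' `TN = round(specificity * n_neg)` with half-up rounding, the remainders
#' being FN and FP. Used to check the internal consistency of published
#' performance tables.
#'
#' @param n_pos,n_neg class sizes.
#' @param sensitivity,specificity proportions in \[0, 1\] (not percentages).
#' @return named numeric `c(TP, FP, FN, TN)`.
#' @export
reconstructConfusion <- function(n_pos, n_neg, sensitivity, specificity) {
  if (n_pos < 0 || n_neg < 0 || sensitivity < 0 || sensitivity > 1 ||
      specificity < 0 || specificity > 1)
    pmStop("inputs out of range", "config_error")
  TP <- roundHalfUp(sensitivity * n_pos)
  TN <- roundHalfUp(specificity * n_neg)
  c(TP = TP, FP = n_neg - TN, FN = n_pos - TP, TN = TN)
}

#' Default tuning grids per tree profile
#'
#' c50: `min_child` 5..30 by 5 and `fn_cost` 1..20 by 1.25;
#' cart: `min_split` 10..40 by 5 and `cp` 0.001..0.1 by 0.001;
#' ci: `mincriterion` 0.1..0.9 by 0.1 plus 0.99, and `min_split` 35..45 by 5.
#'
#' @param profile `"c50"`, `"cart"` or `"ci"`.
#' @return named list of parameter axes (in axis order used for tie-breaks).
#' @export
defaultParamGrid <- function(profile = c("c50", "cart", "ci")) {
  profile <- match.arg(profile)
  switch(profile,
         c50 = list(min_child = seq(5, 30, by = 5),
                    fn_cost = seq(1, 20, by = 1.25)),
         cart = list(min_split = seq(10, 40, by = 5),
                     cp = seq(0.001, 0.1, by = 0.001)),
         ci = list(mincriterion = c(seq(0.1, 0.9, by = 0.1), 0.99),
                   min_split = seq(35, 45, by = 5)))
}

.paramsFromPoint <- function(profile, point, base = list()) {
  args <- c(list(profile = profile), base[setdiff(names(base), names(point))],
            as.list(point))
  do.call(treeParams, args)
}

#' Stratified cross-validated grid search
#'
#' For every grid point, fits the tree profile on each of `folds` stratified
#' training folds and averages the held-out overall agreement rate (plain
#' accuracy; cost weighting affects fitting, never the selection metric).
#' Ties go to the earlier point in axis order. Fold assignment is derived
#' from `seed` once and shared by all grid points.
#'
#' @param train a [PatientTermMatrix-class] view.
#' @param features codes offered to the trees.
#' @param profile tree profile to tune.
#' @param grid named list of parameter axes; default [defaultParamGrid()].
#' @param folds number of folds, `>= 2`; default 10.
#' @param seed integer seed for the fold assignment.
#' @param base fixed tree parameters not on the grid.
#' @return a [GridResult-class].
#' @export
crossValidatedGridSearch <- function(train, features,
                                     profile = c("c50", "cart", "ci"),
                                     grid = NULL, folds = 10L, seed = 1L,
                                     base = list()) {
  profile <- match.arg(profile)
  if (is.null(grid)) grid <- defaultParamGrid(profile)
  if (folds < 2L) pmStop("folds must be >= 2", "config_error")
  y <- outcomeLabels(train)
  fold <- stratifiedFolds(y, folds, seed)
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  agreement <- numeric(nrow(points))
  n_fits <- 0L
  for (p in seq_len(nrow(points))) {
    params <- .paramsFromPoint(profile, points[p, , drop = FALSE], base)
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- train[, fold != f]
      te <- train[, fold == f]
      model <- fitTree(tr, features, params)
      n_fits <- n_fits + 1L
      acc[f] <- mean(predict(model, te) == outcomeLabels(te))
    }
    agreement[p] <- mean(acc)
  }
  tab <- cbind(points, cv_agreement = agreement)
  best <- as.list(points[which.max(agreement), , drop = FALSE])
  new("GridResult", profile = profile, table = tab,
      best = lapply(best, unname), n_fits = n_fits)
}

#' Select the final model across candidate feature lists
#'
#' Refits each candidate (a feature list plus its tuned parameters) on the
#' training view, ranks the refits by validation accuracy with F1 and then
#' fewer-features tie-breaks, and reports the winner's performance on the
#' held-out test view.
#'
#' @param candidates list of `list(features =, profile =, params =)` where
#'   `params` is a named list of tuned values (e.g. `best` from a
#'   [GridResult-class]).
#' @param train,val,test disjoint [PatientTermMatrix-class] views.
#' @param base fixed tree parameters merged under each candidate's tuned ones.
#' @return list with elements `model` ([PhenoTree-class]), `report`
#'   (test-set [PerformanceReport-class]), `winner` (candidate index) and
#'   `validation` (per-candidate validation metrics).
#' @export
selectFinalModel <- function(candidates, train, val, test, base = list()) {
  if (length(candidates) == 0L) pmStop("no candidates", "config_error")
  fits <- vector("list", length(candidates))
  vtab <- data.frame(candidate = seq_along(candidates),
                     n_features = NA_real_, accuracy = NA_real_,
                     f1 = NA_real_)
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    params <- .paramsFromPoint(cand$profile, cand$params, base)
    fits[[k]] <- fitTree(train, cand$features, params)
    m <- .valMetrics(fits[[k]], val)
    vtab$n_features[k] <- length(cand$features)
    vtab$accuracy[k] <- m["accuracy"]
    vtab$f1[k] <- m["f1"]
  }
  ord <- order(-vtab$accuracy, -vtab$f1, vtab$n_features)
  win <- ord[1L]
  truth <- outcomeLabels(test)
  report <- performance(confusionCounts(truth, predict(fits[[win]], test)))
  list(model = fits[[win]], report = report, winner = win, validation = vtab)
}
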