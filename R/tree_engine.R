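# Phase 3 learner: a transparent, cost-aware binary decision-tree engine over
# code-count features, grown greedily with impurity-gain splits at midpoint
# thresholds.
#
# Cost sensitivity: each positive training patient carries weight fn_cost
# (false-positive cost fixed at 1) in every count, impurity and leaf label.
# A leaf predicts positive when fn_cost * n_pos >= n_neg, i.e. whenever the
# expected cost of calling it negative is at least that of calling it
# positive (ties go to the positive class).
#
# Profiles:
#   cart - Gini criterion + cost-complexity pruning at cp (weakest link)
#   c50  - entropy criterion; min_child and fn_cost are the tuned levers
#   ci   - splits additionally gated by a Bonferroni-corrected chi-squared
#          association test: split only if 1 - p_adj >= mincriterion

.impurities <- list(
  gini    = function(q) 2 * q * (1 - q),
  entropy = .entropy2,
  dkm     = function(q) 2 * sqrt(pmax(q * (1 - q), 0))
)

#' Construct validated tree hyper-parameters
#'
#' @param profile `"cart"`, `"c50"` or `"ci"`.
#' @param criterion impurity for split gain; defaults to `"gini"` for
#'   cart/ci and `"entropy"` for c50.
#' @param min_split smallest node size at which a split is attempted
#'   (rpart's `minsplit`); default 20.
#' @param min_child smallest allowed child node (rpart's `minbucket`, C5.0's
#'   `minCases`); default 7.
#' @param fn_cost cost of misclassifying a positive as negative, `>= 1`;
#'   default 1 (cost-insensitive).
#' @param cp complexity parameter in \[0, 1\] for cart pruning; default 0.
#' @param mincriterion 1 minus the p-value a split must beat (ci profile),
#'   in (0, 1); default 0.95.
#' @param seed integer, kept for provenance.
#' @return a [TreeParams-class].
#' @export
treeParams <- function(profile = c("c50", "cart", "ci"), criterion = NULL,
                       min_split = 20, min_child = 7, fn_cost = 1,
                       cp = 0, mincriterion = 0.95, seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(criterion))
    criterion <- if (profile == "c50") "entropy" else "gini"
  criterion <- match.arg(criterion, c("gini", "entropy", "dkm"))
  if (min_split < 1 || min_child < 1)
    pmStop("min_split and min_child must be >= 1", "config_error")
  if (fn_cost < 1) pmStop("fn_cost must be >= 1", "config_error")
  if (cp < 0 || cp > 1) pmStop("cp must lie in [0, 1]", "config_error")
  if (mincriterion <= 0 || mincriterion >= 1)
    pmStop("mincriterion must lie in (0, 1)", "config_error")
  new("TreeParams", profile = profile, criterion = criterion,
      min_split = as.numeric(min_split), min_child = as.numeric(min_child),
      fn_cost = as.numeric(fn_cost), cp = as.numeric(cp),
      mincriterion = as.numeric(mincriterion), seed = as.integer(seed))
}

# best admissible (feature, threshold) split at a node; deterministic
# tie-break: lowest feature column, then smallest threshold
.bestSplit <- function(X, y, w, min_child, impurity) {
  wpos <- sum(w[y == 1]); wneg <- sum(w[y == 0]); wtot <- wpos + wneg
  parent <- impurity(wpos / wtot)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ux <- sort(unique(x))
    if (length(ux) < 2L) next
    # per distinct value: patients, weighted positives, total weight
    grp <- match(x, ux)
    n_v <- tabulate(grp, length(ux))
    wp_v <- vapply(seq_along(ux), function(v) sum(w[grp == v & y == 1]), 0)
    wt_v <- vapply(seq_along(ux), function(v) sum(w[grp == v]), 0)
    nl <- cumsum(n_v)[-length(ux)]
    wl_pos <- cumsum(wp_v)[-length(ux)]
    wl <- cumsum(wt_v)[-length(ux)]
    nr <- length(y) - nl
    wr_pos <- wpos - wl_pos
    wr <- wtot - wl
    ok <- nl >= min_child & nr >= min_child
    if (!any(ok)) next
    gain <- parent - (wl / wtot) * impurity(wl_pos / wl) -
      (wr / wtot) * impurity(wr_pos / wr)
    gain[!ok] <- -Inf
    k <- which.max(gain)                    # first max: smallest threshold
    if (is.null(best) || gain[k] > best$gain + 1e-12)
      best <- list(j = j, threshold = (ux[k] + ux[k + 1L]) / 2,
                   gain = gain[k])
  }
  best
}

.growNode <- function(X, y, w, params, impurity, depth, n_features) {
  wpos <- sum(w[y == 1]); wneg <- sum(w[y == 0])
  node <- list(n_neg = sum(y == 0), n_pos = sum(y == 1),
               w_neg = wneg, w_pos = wpos,
               predicted = if (wpos >= wneg) 1L else 0L,
               depth = depth, split = NULL, children = NULL)
  if (node$n_pos == 0L || node$n_neg == 0L) return(node)       # pure
  if (length(y) < params@min_split) return(node)
  best <- .bestSplit(X, y, w, params@min_child, impurity)
  if (is.null(best) || best$gain <= 1e-12) return(node)
  left <- X[, best$j] <= best$threshold
  if (params@profile == "ci") {
    # gate on the association of the chosen split with the outcome
    tab <- c(A = sum(left & y == 1), B = sum(left & y == 0),
             C = sum(!left & y == 1), D = sum(!left & y == 0))
    p <- pchisq(.chi2Vec(tab["A"], tab["B"], tab["C"], tab["D"])[[1]],
                df = 1, lower.tail = FALSE)
    n_cand <- sum(apply(X, 2, function(col) length(unique(col))) > 1L)
    p_adj <- min(1, p * max(n_cand, 1L))
    if (1 - p_adj < params@mincriterion) return(node)
  }
  node$split <- list(feature = colnames(X)[best$j], threshold = best$threshold)
  node$children <- list(
    left = .growNode(X[left, , drop = FALSE], y[left], w[left], params,
                     impurity, depth + 1L, n_features),
    right = .growNode(X[!left, , drop = FALSE], y[!left], w[!left], params,
                      impurity, depth + 1L, n_features))
  node
}

#' Fit a transparent decision tree
#'
#' Recursive greedy growth on the training view restricted to `features`:
#' every candidate (feature, midpoint-threshold) split is scored by the
#' cost-weighted impurity gain; growth stops when a node is pure, smaller
#' than `min_split`, has no admissible split leaving both children at least
#' `min_child` patients, the best gain is non-positive, or (ci profile) the
#' chosen split fails the Bonferroni-corrected chi-squared gate. For the cart
#' profile with `cp > 0` the grown tree is cost-complexity pruned.
#'
#' @param train a [PatientTermMatrix-class] (the training view).
#' @param features codes offered to the tree (subset of the vocabulary).
#' @param params a [TreeParams-class] from [treeParams()].
#' @return a [PhenoTree-class].
#' @export
fitTree <- function(train, features, params = treeParams()) {
  if (length(features) == 0L)
    pmStop("feature list is empty", "config_error")
  missing <- setdiff(features, codeIDs(train))
  if (length(missing))
    pmStop(paste("features absent from vocabulary:",
                 paste(head(missing, 5), collapse = ", ")), "lookup_error")
  if (ncol(train) == 0L) pmStop("training view is empty", "empty_input_error")
  X <- t(as.matrix(termCounts(train)[features, , drop = FALSE]))
  colnames(X) <- features
  y <- unname(outcomeLabels(train))
  w <- ifelse(y == 1, params@fn_cost, 1)
  impurity <- .impurities[[params@criterion]]
  root <- .growNode(X, y, w, params, impurity, 0L, length(features))
  model <- new("PhenoTree", root = root, params = params, features = features)
  if (params@profile == "cart" && params@cp > 0)
    model <- pruneTree(model, params@cp)
  model
}

# weighted misclassification risk of a node taken as a leaf
.nodeRisk <- function(nd) min(nd$w_pos, nd$w_neg)

# (risk of subtree's leaves, number of leaves)
.subtreeRisk <- function(nd) {
  if (is.null(nd$children)) return(c(.nodeRisk(nd), 1))
  l <- .subtreeRisk(nd$children$left)
  r <- .subtreeRisk(nd$children$right)
  c(l[1] + r[1], l[2] + r[2])
}

# weakest-link value of every internal node, with recursion paths
.linkTable <- function(nd, root_risk, path = integer()) {
  if (is.null(nd$children)) return(NULL)
  sr <- .subtreeRisk(nd)
  g <- if (root_risk > 0)
    (.nodeRisk(nd) - sr[1]) / ((sr[2] - 1) * root_risk) else 0
  rbind(data.frame(g = g, path = I(list(path))),
        .linkTable(nd$children$left, root_risk, c(path, 1L)),
        .linkTable(nd$children$right, root_risk, c(path, 2L)))
}

.collapseAt <- function(nd, path) {
  if (length(path) == 0L) {
    nd$split <- NULL
    nd$children <- NULL
    return(nd)
  }
  side <- if (path[1L] == 1L) "left" else "right"
  nd$children[[side]] <- .collapseAt(nd$children[[side]], path[-1L])
  nd
}

#' Cost-complexity pruning
#'
#' Repeatedly collapses the internal node whose per-split relative risk
#' reduction (risk saved by its subtree, per extra leaf, relative to the
#' root risk) is smallest, while that value is below `cp`. `cp = 0` leaves
#' the tree unchanged; large `cp` collapses it towards a single leaf.
#'
#' @param model a [PhenoTree-class].
#' @param cp complexity threshold, `>= 0`.
#' @return the pruned [PhenoTree-class].
#' @export
pruneTree <- function(model, cp) {
  if (cp < 0) pmStop("cp must be >= 0", "config_error")
  root <- model@root
  root_risk <- .nodeRisk(root)
  repeat {
    links <- .linkTable(root, root_risk)
    if (is.null(links) || nrow(links) == 0L) break
    k <- which.min(links$g)
    if (links$g[k] >= cp) break
    root <- .collapseAt(root, links$path[[k]])
  }
  new("PhenoTree", root = root, params = model@params,
      features = model@features)
}

.routePredict <- function(nd, X, idx, out) {
  if (is.null(nd$children)) {
    out[idx] <- nd$predicted
    return(out)
  }
  xv <- X[idx, nd$split$feature]
  left <- xv <= nd$split$threshold
  out <- .routePredict(nd$children$left, X, idx[left], out)
  .routePredict(nd$children$right, X, idx[!left], out)
}

#' Predict outcomes for patients
#'
#' Routes each patient down the tree by its code counts. Codes used by the
#' tree but absent from `newdata`'s vocabulary count as 0 (a code that was
#' never recorded is an absent code).
#'
#' @param object a [PhenoTree-class].
#' @param newdata a [PatientTermMatrix-class] or a patients-by-codes matrix.
#' @param ... ignored.
#' @return named integer vector of 0/1 predictions.
#' @export
setMethod("predict", "PhenoTree", function(object, newdata, ...) {
  used <- unique(unlist(lapply(exportRules(object)$literals,
                               function(l) vapply(l, `[[`, "", "feature"))))
  if (is(newdata, "PatientTermMatrix")) {
    have <- intersect(used, codeIDs(newdata))
    X <- matrix(0, ncol(newdata), length(used),
                dimnames = list(patientIDs(newdata), used))
    if (length(have))
      X[, have] <- t(as.matrix(termCounts(newdata)[have, , drop = FALSE]))
  } else {
    X <- as.matrix(newdata)
    add <- setdiff(used, colnames(X))
    if (length(add)) {
      X <- cbind(X, matrix(0, nrow(X), length(add),
                           dimnames = list(rownames(X), add)))
    }
  }
  if (length(used) == 0L)       # root-leaf tree never consults a feature
    X <- matrix(0, nrow(X), 1, dimnames = list(rownames(X), "dummy"))
  out <- integer(nrow(X))
  out <- .routePredict(object@root, X, seq_len(nrow(X)), out)
  setNames(as.integer(out), rownames(X))
})

.collectRules <- function(nd, literals) {
  if (is.null(nd$children)) {
    n <- nd$n_neg + nd$n_pos
    conf <- if (n > 0)
      (if (nd$predicted == 1L) nd$n_pos else nd$n_neg) / n else NA_real_
    return(list(list(literals = literals, predicted = nd$predicted,
                     support = n, confidence = conf)))
  }
  f <- nd$split$feature; t <- nd$split$threshold
  c(.collectRules(nd$children$left,
                  c(literals, list(list(feature = f, op = "<=", threshold = t)))),
    .collectRules(nd$children$right,
                  c(literals, list(list(feature = f, op = ">", threshold = t)))))
}

.literalText <- function(l, dict) {
  # counts are integers and thresholds midpoints, so "x <= 1.5" prints "x <= 1"
  thr <- floor(l$threshold)
  desc <- if (!is.null(dict) && l$feature %in% names(dict))
    sprintf(" [%s]", dict[[l$feature]]) else ""
  sprintf("%s%s %s %d", l$feature, desc, l$op, thr)
}

#' Export a fitted tree as decision rules
#'
#' One rule per leaf, literals in root-to-leaf order; mutually exclusive and
#' exhaustive over the feature space. Code descriptions from a dictionary are
#' attached when available.
#'
#' @param model a [PhenoTree-class].
#' @param dict optional named character vector from [readCodeDictionary()].
#' @return `data.frame` with columns `rule`, `predicted`, `support`,
#'   `confidence`, `text` (the printable form) and a `literals` list-column.
#' @export
exportRules <- function(model, dict = NULL) {
  rules <- .collectRules(model@root, list())
  text <- vapply(rules, function(r) {
    cond <- if (length(r$literals) == 0L) "TRUE" else
      paste(vapply(r$literals, .literalText, "", dict = dict),
            collapse = " AND ")
    sprintf("IF %s THEN %d (support=%d, confidence=%.2f)",
            cond, r$predicted, r$support, r$confidence)
  }, "")
  data.frame(rule = seq_along(rules),
             predicted = vapply(rules, `[[`, 0L, "predicted"),
             support = vapply(rules, `[[`, 0L, "support"),
             confidence = vapply(rules, `[[`, 0, "confidence"),
             text = text,
             literals = I(lapply(rules, `[[`, "literals")),
             stringsAsFactors = FALSE)
}

#' Serialize / reload a fitted tree as JSON
#'
#' @param model a [PhenoTree-class].
#' @param path destination / source file.
#' @export
writeTreeModel <- function(model, path) {
  .checkWritable(path)
  p <- model@params
  jsonlite::write_json(list(
    params = list(profile = p@profile, criterion = p@criterion,
                  min_split = p@min_split, min_child = p@min_child,
                  fn_cost = p@fn_cost, cp = p@cp,
                  mincriterion = p@mincriterion, seed = p@seed),
    features = model@features,
    root = model@root), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeTreeModel
#' @export
readTreeModel <- function(path) {
  if (!file.exists(path)) pmStop(paste("no such file:", path), "io_error")
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fixNode <- function(nd) {
    nd$predicted <- as.integer(nd$predicted)
    # leaves serialize their NULL split/children as empty objects
    if (length(nd$split) == 0L) nd$split <- NULL
    if (length(nd$children) == 0L) nd$children <- NULL
    if (!is.null(nd$children)) {
      nd$children$left <- fixNode(nd$children$left)
      nd$children$right <- fixNode(nd$children$right)
    }
    nd
  }
  p <- x$params
  new("PhenoTree", root = fixNode(x$root),
      params = treeParams(profile = p$profile, criterion = p$criterion,
                          min_split = p$min_split, min_child = p$min_child,
                          fn_cost = p$fn_cost, cp = p$cp,
                          mincriterion = p$mincriterion, seed = p$seed),
      features = x$features)
}
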