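# Phase 2a: score every code's association with the outcome on a 2x2
# presence/absence contingency table and emit ranked feature lists.
#
# All five indices operate on the same binarized table (presence = count >= 1):
#   A = positives with the code, B = negatives with the code,
#   C = positives without,      D = negatives without.
# Codes present in every patient or in none carry no discriminative signal
# and score 0 under every index.

.entropy2 <- function(q) {
  h <- numeric(length(q))
  ok <- q > 0 & q < 1
  qq <- q[ok]
  h[ok] <- -qq * log2(qq) - (1 - qq) * log2(1 - qq)
  h
}

# parent impurity minus child-size-weighted child impurities, vectorized
.impurityGain <- function(A, B, C, D, impurity) {
  N <- A + B + C + D
  qp <- (A + C) / N
  nl <- A + B
  nr <- C + D
  ql <- ifelse(nl > 0, A / nl, 0)
  qr <- ifelse(nr > 0, C / nr, 0)
  g <- impurity(qp) - (nl / N) * impurity(ql) - (nr / N) * impurity(qr)
  pmax(g, 0)
}

.checkTable <- function(t) {
  if (!all(c("A", "B", "C", "D") %in% names(t)))
    pmStop("contingency table needs named entries A, B, C, D", "config_error")
  if (any(t < 0) || sum(t) <= 0)
    pmStop("contingency counts must be >= 0 with positive total", "config_error")
  t
}

.degenerate <- function(A, B, C, D) (A + B) == 0 | (C + D) == 0

#' 2x2 presence/outcome contingency table for one code
#'
#' Binarizes the code's counts (presence = at least one occurrence) over a
#' patient subset and cross-tabulates against the outcome.
#'
#' @param x a [PatientTermMatrix-class].
#' @param code a vocabulary code.
#' @param subset patient ids to restrict to (default: all patients).
#' @return named numeric `c(A, B, C, D)`: positives/negatives with the code,
#'   positives/negatives without it.
#' @export
contingency <- function(x, code, subset = NULL) {
  if (!code %in% codeIDs(x))
    pmStop(paste("unknown code:", code), "lookup_error")
  if (!is.null(subset)) x <- x[, subset]
  pres <- as.vector(termCounts(x)[code, ]) >= 1
  y <- outcomeLabels(x)
  c(A = sum(pres & y == 1), B = sum(pres & y == 0),
    C = sum(!pres & y == 1), D = sum(!pres & y == 0))
}

#' Association indices on a 2x2 contingency table
#'
#' The five ranking indices. `chi2Score()` is the Pearson chi-squared
#' statistic `N(AD - BC)^2 / ((A+B)(C+D)(A+C)(B+D))`. `giniGain()`,
#' `infoGain()` and `dkmGain()` are impurity gains — parent impurity minus
#' size-weighted child impurities — with impurity `2q(1-q)`, Shannon entropy
#' in bits, and `2*sqrt(q(1-q))` respectively, where `q` is the
#' positive-class proportion. `binomialScore()` is the -log10 one-sided exact
#' binomial tail `P(X >= A)` for `X ~ Binomial(A+B, (A+C)/N)`: how surprising
#' the code's concentration in positives is under the class-prevalence null.
#' All are `>= 0`, zero on exact independence, and zero by convention when a
#' margin is degenerate (code present in all patients or none).
#'
#' @param t named numeric `c(A, B, C, D)` from [contingency()].
#' @return single non-negative score.
#' @export
chi2Score <- function(t) {
  t <- .checkTable(t)
  .chi2Vec(t["A"], t["B"], t["C"], t["D"])[[1]]
}

.chi2Vec <- function(A, B, C, D) {
  A <- as.numeric(A); B <- as.numeric(B)
  C <- as.numeric(C); D <- as.numeric(D)   # doubles: margin products overflow int
  N <- A + B + C + D
  den <- (A + B) * (C + D) * (A + C) * (B + D)
  ifelse(den > 0, N * (A * D - B * C)^2 / den, 0)
}

#' @rdname chi2Score
#' @export
giniGain <- function(t) {
  t <- .checkTable(t)
  .giniVec(t["A"], t["B"], t["C"], t["D"])[[1]]
}

.giniVec <- function(A, B, C, D)
  ifelse(.degenerate(A, B, C, D), 0,
         .impurityGain(A, B, C, D, function(q) 2 * q * (1 - q)))

#' @rdname chi2Score
#' @export
infoGain <- function(t) {
  t <- .checkTable(t)
  .igVec(t["A"], t["B"], t["C"], t["D"])[[1]]
}

.igVec <- function(A, B, C, D)
  ifelse(.degenerate(A, B, C, D), 0, .impurityGain(A, B, C, D, .entropy2))

#' @rdname chi2Score
#' @export
dkmGain <- function(t) {
  t <- .checkTable(t)
  .dkmVec(t["A"], t["B"], t["C"], t["D"])[[1]]
}

.dkmVec <- function(A, B, C, D)
  ifelse(.degenerate(A, B, C, D), 0,
         .impurityGain(A, B, C, D, function(q) 2 * sqrt(q * (1 - q))))

#' @rdname chi2Score
#' @export
binomialScore <- function(t) {
  t <- .checkTable(t)
  .binomVec(t["A"], t["B"], t["C"], t["D"])[[1]]
}

.binomVec <- function(A, B, C, D) {
  N <- A + B + C + D
  p0 <- (A + C) / N
  score <- -pbinom(A - 1, A + B, p0, lower.tail = FALSE, log.p = TRUE) / log(10)
  score[.degenerate(A, B, C, D) | A == 0 | p0 %in% c(0, 1)] <- 0
  pmax(score, 0)
}

.scoreFuns <- list(chi2 = .chi2Vec, gini = .giniVec, info_gain = .igVec,
                   dkm = .dkmVec, binomial = .binomVec)

#' Rank all vocabulary codes by an association index
#'
#' Scores every code on the chosen subset (typically the training split) and
#' returns the ranked list, descending by score with deterministic
#' lexicographic tie-breaking.
#'
#' @param x a [PatientTermMatrix-class].
#' @param method `"chi2"`, `"gini"`, `"info_gain"`, `"dkm"` or `"binomial"`.
#' @param subset patient ids to score on (default: all); must span both
#'   classes.
#' @return a [RankedFeatures-class].
#' @export
rankFeatures <- function(x, method = c("chi2", "gini", "info_gain", "dkm",
                                       "binomial"), subset = NULL) {
  method <- match.arg(method)
  if (!is.null(subset)) x <- x[, subset]
  y <- outcomeLabels(x)
  if (length(unique(y)) < 2L)
    pmStop("subset must contain both outcome classes", "degenerate_label_error")
  pres <- termCounts(x) >= 1
  A <- Matrix::rowSums(pres[, y == 1, drop = FALSE])
  B <- Matrix::rowSums(pres[, y == 0, drop = FALSE])
  C <- sum(y == 1) - A
  D <- sum(y == 0) - B
  score <- .scoreFuns[[method]](A, B, C, D)
  codes <- codeIDs(x)
  # sort on a 10-significant-digit key: codes whose scores agree up to
  # floating-point noise are true ties and fall back to lexicographic order
  ord <- order(-signif(score, 10), codes, method = "radix")
  new("RankedFeatures", method = method,
      ranking = data.frame(rank = seq_along(codes), code = codes[ord],
                           score = as.numeric(score[ord]),
                           stringsAsFactors = FALSE))
}
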