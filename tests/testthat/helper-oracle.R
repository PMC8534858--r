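# Independent oracles, written naively and kept separate from the package
# code paths they check.

# Shannon entropy (bits) of a binary proportion
oracleEntropy <- function(q) {
  if (q <= 0 || q >= 1) return(0)
  -q * log2(q) - (1 - q) * log2(1 - q)
}

# impurity gain evaluated cell-by-cell from first principles
oracleGain <- function(A, B, C, D, imp) {
  A <- unname(A); B <- unname(B); C <- unname(C); D <- unname(D)
  N <- A + B + C + D
  nl <- A + B; nr <- C + D
  parent <- imp((A + C) / N)
  left <- if (nl > 0) imp(A / nl) else 0
  right <- if (nr > 0) imp(C / nr) else 0
  parent - (nl / N) * left - (nr / N) * right
}

# exact one-sided binomial tail by explicit summation
oracleBinomTail <- function(A, n, p) {
  if (A <= 0) return(1)
  sum(vapply(A:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k), 0))
}

# Brute-force exhaustive-split decision tree: at every node, loop over every
# (feature, midpoint threshold) pair, score the weighted Gini gain directly,
# apply the same stopping rules and tie-breaks (lowest feature, smallest
# threshold), and predict by expected cost. Meant for <= 6 patients.
oracleTreePredict <- function(X, y, w, min_split, min_child, newX = X) {
  grow <- function(idx) {
    wp <- sum(w[idx][y[idx] == 1]); wn <- sum(w[idx][y[idx] == 0])
    pred <- if (wp >= wn) 1L else 0L
    leaf <- list(pred = pred, split = NULL)
    if (wp == 0 || wn == 0 || length(idx) < min_split) return(leaf)
    gini <- function(ids) {
      a <- sum(w[ids][y[ids] == 1]); b <- sum(w[ids][y[ids] == 0])
      if (a + b == 0) return(0)
      q <- a / (a + b)
      2 * q * (1 - q)
    }
    wtot <- wp + wn
    best <- NULL
    for (j in seq_len(ncol(X))) {
      ux <- sort(unique(X[idx, j]))
      if (length(ux) < 2) next
      for (t in (ux[-1] + ux[-length(ux)]) / 2) {
        l <- idx[X[idx, j] <= t]; r <- idx[X[idx, j] > t]
        if (length(l) < min_child || length(r) < min_child) next
        wl <- sum(w[l]); wr <- sum(w[r])
        g <- gini(idx) - (wl / wtot) * gini(l) - (wr / wtot) * gini(r)
        if (is.null(best) || g > best$g + 1e-12) best <- list(j = j, t = t, g = g)
      }
    }
    if (is.null(best) || best$g <= 1e-12) return(leaf)
    list(pred = pred, split = best,
         left = grow(idx[X[idx, best$j] <= best$t]),
         right = grow(idx[X[idx, best$j] > best$t]))
  }
  root <- grow(seq_len(nrow(X)))
  route <- function(node, x) {
    if (is.null(node$split)) return(node$pred)
    if (x[node$split$j] <= node$split$t) route(node$left, x)
    else route(node$right, x)
  }
  apply(newX, 1, function(x) route(root, x))
}
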