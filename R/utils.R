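#' @import methods
#' @importFrom stats pbinom pchisq rbinom rpois predict setNames
#' @importFrom utils read.csv write.csv read.delim write.table head
#' @importFrom tools md5sum
NULL

# classed conditions so callers/tests can discriminate failure modes
pmStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("phenominer_", class), "phenominer_error")))
}

# run `expr` with the global RNG seeded to `seed`, restoring prior RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# confusion counts are integers; round() is banker's, we need half-up
roundHalfUp <- function(x) floor(x + 0.5)

# stratified assignment of indices by label into parts with given fractions;
# per-class part sizes differ from fraction*class size by at most 1
stratifiedAssign <- function(labels, fractions, seed) {
  parts <- names(fractions)
  assignment <- character(length(labels))
  withSeed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      sizes <- floor(fractions * n)
      rem <- n - sum(sizes)
      if (rem > 0) {
        extra <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(rem)]
        sizes[extra] <- sizes[extra] + 1L
      }
      at <- 0L
      for (p in seq_along(parts)) {
        take <- idx[at + seq_len(sizes[p])]
        assignment[take] <- parts[p]
        at <- at + sizes[p]
      }
    }
  })
  assignment
}

# stratified k-fold: returns integer fold id per element, each class spread
# as evenly as possible across folds
stratifiedFolds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      if (length(idx) < k)
        pmStop(sprintf("class '%s' has %d members, fewer than %d folds",
                       cls, length(idx), k), "stratification_error")
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}
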