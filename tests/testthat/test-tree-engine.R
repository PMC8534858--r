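test_that("parameter validation enforces the documented ranges", {
  expect_error(treeParams(fn_cost = 0.5), class = "phenominer_config_error")
  expect_error(treeParams(cp = 1.5), class = "phenominer_config_error")
  expect_error(treeParams(mincriterion = 1), class = "phenominer_config_error")
  expect_error(treeParams(min_split = 0), class = "phenominer_config_error")
  expect_equal(treeParams("c50")@criterion, "entropy")
  expect_equal(treeParams("cart")@criterion, "gini")
})

test_that("a perfectly predictive code yields a single accurate stump", {
  counts <- cbind(sig = c(1, 1, 1, 0, 0, 0), noise = c(1, 0, 1, 0, 1, 0))
  ptm <- ptmFromCounts(counts, c(1L, 1L, 1L, 0L, 0L, 0L))
  m <- fitTree(ptm, c("sig", "noise"), treeParams(min_split = 2, min_child = 1))
  expect_equal(nodeCount(m), 3L)
  expect_equal(m@root$split$feature, "sig")
  expect_equal(unname(predict(m, ptm)), outcomeLabels(ptm), ignore_attr = TRUE)
})

test_that("pure nodes and empty feature lists follow their contracts", {
  counts <- matrix(rep(1, 5), 5, 1, dimnames = list(NULL, "X"))
  ptm <- ptmFromCounts(counts, rep(1L, 5))
  m <- fitTree(ptm, "X", treeParams(min_split = 2, min_child = 1))
  expect_equal(nodeCount(m), 1L)
  expect_error(fitTree(ptm, character()), class = "phenominer_config_error")
  expect_error(fitTree(ptm, "missing"), class = "phenominer_lookup_error")
})

test_that("leaf labels minimize expected misclassification cost", {
  # 1 positive vs 3 negatives in one unsplittable node:
  # predicting negative costs fn_cost, predicting positive costs 3
  counts <- matrix(1, 4, 1, dimnames = list(NULL, "X"))
  ptm <- ptmFromCounts(counts, c(1L, 0L, 0L, 0L))
  leaf <- function(fn_cost)
    fitTree(ptm, "X", treeParams(fn_cost = fn_cost))@root$predicted
  expect_equal(leaf(1), 0L)
  expect_equal(leaf(2), 0L)
  expect_equal(leaf(3), 1L)   # tie goes to the positive class
  expect_equal(leaf(4), 1L)
})

test_that("child class counts sum to the parent's at every split", {
  fx <- goldenFixture("as_like")
  ptm <- buildPatientTermMatrix(fx$events, fx$labels)
  m <- fitTree(ptm, c("N100.", "F440."), treeParams(fn_cost = 3))
  check <- function(nd) {
    if (is.null(nd$children)) return(invisible())
    expect_equal(nd$children$left$n_pos + nd$children$right$n_pos, nd$n_pos)
    expect_equal(nd$children$left$n_neg + nd$children$right$n_neg, nd$n_neg)
    check(nd$children$left); check(nd$children$right)
  }
  check(m@root)
})

test_that("pruning is the identity at cp 0, total for large cp, monotone between", {
  fx <- tinyImbalanced()
  ptm <- buildPatientTermMatrix(fx$events, fx$labels)
  feats <- codeIDs(ptm)
  m <- fitTree(ptm, feats, treeParams(profile = "cart", min_split = 4,
                                      min_child = 2, fn_cost = 4))
  expect_gt(nodeCount(m), 1L)
  expect_equal(nodeCount(pruneTree(m, 0)), nodeCount(m))
  expect_equal(nodeCount(pruneTree(m, 1)), 1L)
  sizes <- vapply(c(0, 0.01, 0.05, 0.2, 0.5, 1), function(cp)
    nodeCount(pruneTree(m, cp)), 0L)
  expect_true(all(diff(sizes) <= 0L))
  expect_error(pruneTree(m, -0.1), class = "phenominer_config_error")
})

test_that("prediction routes counts through thresholds, absent codes count 0", {
  counts <- cbind(X = c(0, 0, 2, 3), Y = c(1, 1, 0, 0))
  ptm <- ptmFromCounts(counts, c(0L, 0L, 1L, 1L))
  m <- fitTree(ptm, c("X", "Y"), treeParams(min_split = 2, min_child = 1))
  expect_equal(m@root$split$feature, "X")
  # raw matrix input, including a patient with no codes at all
  newx <- rbind(a = c(X = 2, Y = 0), b = c(X = 0, Y = 5), c = c(X = 0, Y = 0))
  expect_equal(unname(predict(m, newx)), c(1L, 0L, 0L))
  # matrix missing the split column entirely: treated as all-zero
  expect_equal(unname(predict(m, rbind(d = c(Y = 1)))), 0L)
  # self-consistency on training data
  expect_equal(unname(predict(m, ptm)), outcomeLabels(ptm), ignore_attr = TRUE)
})

test_that("rules partition the training patients and carry descriptions", {
  fx <- tinySeparable()
  ptm <- buildPatientTermMatrix(fx$events, fx$labels)
  m <- fitTree(ptm, codeIDs(ptm), treeParams(min_split = 2, min_child = 1))
  rules <- exportRules(m)
  expect_equal(nrow(rules), leafCount(m))
  # every patient satisfies exactly one rule
  X <- t(as.matrix(termCounts(ptm)))
  satisfied <- vapply(seq_len(nrow(X)), function(i) {
    hits <- vapply(rules$literals, function(lits) {
      all(vapply(lits, function(l) {
        v <- if (l$feature %in% colnames(X)) X[i, l$feature] else 0
        if (l$op == "<=") v <= l$threshold else v > l$threshold
      }, TRUE))
    }, TRUE)
    sum(hits)
  }, 0L)
  expect_true(all(satisfied == 1L))
  expect_equal(sum(rules$support), ncol(ptm))

  dict <- readCodeDictionary(system.file("extdata", "code_dictionary.csv",
                                         package = "PhenoMiner"))
  annotated <- exportRules(m, dict)
  expect_true(any(grepl("Ankylosing spondylitis", annotated$text)))
  # a stump exports exactly two mutually exclusive rules
  stump <- fitTree(ptm, "N100.", treeParams(min_split = 2, min_child = 1))
  expect_equal(nrow(exportRules(stump)), 2L)
})

test_that("raising the false-negative cost never shrinks positive calls", {
  fx <- tinyImbalanced()
  ptm <- buildPatientTermMatrix(fx$events, fx$labels)
  feats <- codeIDs(ptm)
  npos <- vapply(seq(1, 20, by = 1.25), function(w)
    sum(predict(fitTree(ptm, feats, treeParams(fn_cost = w)), ptm)), 0)
  expect_true(all(diff(npos) >= 0))
})

test_that("all three criteria reach purity on cleanly separable data", {
  counts <- cbind(sig = c(2, 2, 2, 0, 0, 0, 0, 0), noise = c(1, 0, 1, 0, 1, 0, 1, 0))
  ptm <- ptmFromCounts(counts, c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
  for (crit in c("gini", "entropy", "dkm")) {
    m <- fitTree(ptm, c("sig", "noise"),
                 treeParams(criterion = crit, min_split = 2, min_child = 1))
    expect_equal(unname(predict(m, ptm)), outcomeLabels(ptm),
                 ignore_attr = TRUE)
  }
})

test_that("ci profile stops splitting when the association test fails", {
  # weak split: should pass a lax gate and fail a strict one
  counts <- cbind(w = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0, 1, 0))
  y <- c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L)
  ptm <- ptmFromCounts(counts, y)
  lax <- fitTree(ptm, "w", treeParams(profile = "ci", mincriterion = 0.01,
                                      min_split = 2, min_child = 1))
  strict <- fitTree(ptm, "w", treeParams(profile = "ci", mincriterion = 0.99,
                                         min_split = 2, min_child = 1))
  expect_gt(nodeCount(lax), nodeCount(strict))
  expect_equal(nodeCount(strict), 1L)
})

test_that("cart profile with unit cost agrees with rpart on clean data", {
  skip_if_not_installed("rpart")
  fx <- tinySeparable()
  ptm <- buildPatientTermMatrix(fx$events, fx$labels)
  m <- fitTree(ptm, codeIDs(ptm),
               treeParams(profile = "cart", min_split = 4, min_child = 2))
  df <- as.data.frame(t(as.matrix(termCounts(ptm))))
  names(df) <- make.names(names(df))
  df$y <- factor(outcomeLabels(ptm))
  rp <- rpart::rpart(y ~ ., df, method = "class",
                     control = rpart::rpart.control(minsplit = 4, minbucket = 2,
                                                    cp = 0, xval = 0))
  expect_equal(unname(predict(m, ptm)),
               as.integer(as.character(predict(rp, df, type = "class"))))
})
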