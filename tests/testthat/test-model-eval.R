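test_that("the six metrics follow their definitions, NA on zero denominators", {
  rep <- performance(c(TP = 213, FP = 47, FN = 82, TN = 592))
  m <- metrics(rep)
  expect_equal(unname(m["accuracy"]), 805 / 934, tolerance = 1e-12)
  expect_equal(unname(m["sensitivity"]), 213 / 295, tolerance = 1e-12)
  expect_equal(unname(m["specificity"]), 592 / 639, tolerance = 1e-12)
  expect_equal(unname(m["ppv"]), 213 / 260, tolerance = 1e-12)
  expect_equal(unname(m["npv"]), 592 / 674, tolerance = 1e-12)

  perfect <- metrics(performance(c(TP = 10, FP = 0, FN = 0, TN = 10)))
  expect_true(all(perfect == 1))

  # no predicted positives: ppv undefined, reported NA rather than 0
  m0 <- metrics(performance(c(TP = 0, FP = 0, FN = 5, TN = 15)))
  expect_true(is.na(m0["ppv"]))
  expect_true(is.na(m0["f1"]))
  expect_equal(unname(m0["specificity"]), 1)
  expect_error(performance(c(TP = -1, FP = 0, FN = 0, TN = 1)),
               class = "phenominer_config_error")
})

test_that("F1 is the harmonic mean of precision and recall", {
  # precision = recall = 0.75 -> F1 = 0.75 (e.g. TP=3, FP=1, FN=1)
  m <- metrics(performance(c(TP = 3, FP = 1, FN = 1, TN = 5)))
  expect_equal(unname(m["ppv"]), 0.75)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["f1"]), 0.75)
  # asymmetric case against the closed form
  m2 <- metrics(performance(c(TP = 6, FP = 2, FN = 6, TN = 10)))
  p <- 6 / 8; r <- 6 / 12
  expect_equal(unname(m2["f1"]), 2 * p * r / (p + r), tolerance = 1e-12)
  # zero recall and precision -> harmonic mean undefined
  expect_true(is.na(metrics(performance(c(TP = 0, FP = 3, FN = 4,
                                          TN = 10)))["f1"]))
})

test_that("confusion reconstruction inverts printed sensitivity/specificity", {
  expect_equal(reconstructConfusion(295, 639, 0.722, 0.9264),
               c(TP = 213, FP = 47, FN = 82, TN = 592))
  expect_equal(reconstructConfusion(41, 893, 1.0, 1.0),
               c(TP = 41, FP = 0, FN = 0, TN = 893))
  # half-up rounding, not banker's
  expect_equal(reconstructConfusion(10, 10, 0.25, 0.35)[["TP"]], 3)
  # recovery of the input rates within half-count rounding error
  tabs <- randomTables(25, seed = 13, max_cell = 400)
  for (k in seq_len(nrow(tabs))) {
    n_pos <- tabs$A[k] + tabs$C[k]
    n_neg <- tabs$B[k] + tabs$D[k]
    sens <- round(tabs$A[k] / n_pos, 4)
    spec <- round(tabs$D[k] / n_neg, 4)
    m <- metrics(performance(reconstructConfusion(n_pos, n_neg, sens, spec)))
    expect_lt(abs(m[["sensitivity"]] - sens), 0.5 / n_pos + 1e-9)
    expect_lt(abs(m[["specificity"]] - spec), 0.5 / n_neg + 1e-9)
  }
  expect_error(reconstructConfusion(10, 10, 1.2, 0.5),
               class = "phenominer_config_error")
})

test_that("grid search averages stratified held-out agreement deterministically", {
  fx <- goldenFixture("as_like")
  ptm <- buildPatientTermMatrix(fx$events, fx$labels)
  plan <- splitPatients(ptm, seed = 4)
  tr <- splitPart(ptm, plan, "train")
  grid <- list(min_child = c(2, 5), fn_cost = c(1, 5, 10))
  gr <- crossValidatedGridSearch(tr, c("N100.", "F440."), "c50", grid = grid,
                                 folds = 5, seed = 11)
  expect_equal(nrow(gridTable(gr)), 6L)
  expect_equal(gridFits(gr), 5L * 6L)       # folds x grid points
  expect_true(all(gridTable(gr)$cv_agreement >= 0 &
                  gridTable(gr)$cv_agreement <= 1))
  best <- gridTable(gr)[which.max(gridTable(gr)$cv_agreement), ]
  expect_equal(bestParams(gr)$fn_cost, best$fn_cost)
  gr2 <- crossValidatedGridSearch(tr, c("N100.", "F440."), "c50", grid = grid,
                                  folds = 5, seed = 11)
  expect_identical(gridTable(gr), gridTable(gr2))
  # single-point grid degenerates to plain CV of that point
  g1 <- crossValidatedGridSearch(tr, "N100.", "c50",
                                 grid = list(min_child = 5, fn_cost = 1),
                                 folds = 5, seed = 1)
  expect_equal(nrow(gridTable(g1)), 1L)
  expect_error(crossValidatedGridSearch(tr, "N100.", "c50", folds = 1),
               class = "phenominer_config_error")
  expect_error(crossValidatedGridSearch(tr, "N100.", "c50",
                                        grid = list(min_child = 5, fn_cost = 1),
                                        folds = 50),
               class = "phenominer_stratification_error")
})

test_that("perfectly separable data attains cross-validated agreement 1", {
  counts <- cbind(sig = rep(c(2, 0), c(20, 20)), bg = rep(1, 40))
  ptm <- ptmFromCounts(counts, rep(c(1L, 0L), c(20, 20)),
                       patients = sprintf("s%02d", 1:40))
  gr <- crossValidatedGridSearch(ptm, c("sig", "bg"), "c50",
                                 grid = list(min_child = c(2, 5), fn_cost = 1),
                                 folds = 4, seed = 2,
                                 base = list(min_split = 4))
  expect_equal(max(gridTable(gr)$cv_agreement), 1.0)
})

test_that("final selection ranks by validation accuracy with parsimony ties", {
  counts <- cbind(sig = rep(c(2, 0), c(30, 30)),
                  half = c(rep(1, 15), rep(0, 45)),
                  bg = rep(1, 60))
  ptm <- ptmFromCounts(counts, rep(c(1L, 0L), c(30, 30)),
                       patients = sprintf("t%02d", 1:60))
  plan <- splitPatients(ptm, seed = 6)
  tr <- splitPart(ptm, plan, "train")
  va <- splitPart(ptm, plan, "validation")
  te <- splitPart(ptm, plan, "test")
  base <- list(min_split = 4, min_child = 2)
  cands <- list(
    list(features = c("half", "bg"), profile = "c50",
         params = list(min_child = 2, fn_cost = 1)),
    list(features = "sig", profile = "c50",
         params = list(min_child = 2, fn_cost = 1)),
    list(features = c("sig", "bg"), profile = "c50",
         params = list(min_child = 2, fn_cost = 1)))
  res <- selectFinalModel(cands, tr, va, te, base = base)
  # the dominant predictor wins; among tied candidates, the fewer-feature one
  expect_equal(res$winner, 2L)
  expect_equal(unname(metrics(res$report)["accuracy"]), 1.0)
  one <- selectFinalModel(cands[1], tr, va, te, base = base)
  expect_equal(one$winner, 1L)
  expect_s4_class(one$report, "PerformanceReport")
  expect_error(selectFinalModel(list(), tr, va, te),
               class = "phenominer_config_error")
})

test_that("the full pipeline recovers a deterministic planted signal", {
  # noise-free limit: the planted code is present iff the patient is positive
  n <- 240
  y <- rep(c(1L, 0L), c(24, 216))
  counts <- withr::with_seed(17, cbind(
    D100. = ifelse(y == 1, 1 + rpois(n, 1), 0),
    matrix(rpois(n * 12, 0.5), n, 12,
           dimnames = list(NULL, sprintf("Z%03d.", 1:12)))))
  ptm <- ptmFromCounts(counts, y, patients = sprintf("u%03d", seq_len(n)))
  plan <- splitPatients(ptm, seed = 9)
  tr <- splitPart(ptm, plan, "train")
  va <- splitPart(ptm, plan, "validation")
  te <- splitPart(ptm, plan, "test")
  rk <- rankFeatures(ptm, "chi2", subset = patientIDs(tr))
  expect_equal(topCodes(rk, 1), "D100.")
  trace <- forwardSelect(rk, tr, va, i_max = 8)
  expect_true(fitCount(trace) <= 8L)
  fs <- featureSubsets(trace, rk)
  gr <- crossValidatedGridSearch(tr, fs$best, "c50",
                                 grid = list(min_child = c(2, 5),
                                             fn_cost = c(1, 5)),
                                 folds = 4, seed = 3)
  res <- selectFinalModel(list(list(features = fs$best, profile = "c50",
                                    params = bestParams(gr))), tr, va, te)
  expect_gte(unname(metrics(res$report)["accuracy"]), 0.95)
})
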