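# Builders used across the suite: everything constructed in code.

# event/label tables from a patients-by-codes count matrix
cohortFromCounts <- function(counts, outcome,
                             patients = sprintf("p%02d", seq_len(nrow(counts))),
                             codes = colnames(counts)) {
  stopifnot(!is.null(codes))
  rows <- which(counts > 0, arr.ind = TRUE)
  events <- data.frame(
    patient_id = rep(patients[rows[, 1]], counts[rows]),
    code = rep(codes[rows[, 2]], counts[rows]),
    stringsAsFactors = FALSE)
  events <- events[order(match(events$patient_id, patients)), , drop = FALSE]
  rownames(events) <- NULL
  list(events = events,
       labels = data.frame(patient_id = patients, outcome = outcome,
                           stringsAsFactors = FALSE))
}

ptmFromCounts <- function(counts, outcome, ...) {
  fx <- cohortFromCounts(counts, outcome, ...)
  # pass the vocabulary explicitly so all-zero columns survive
  buildPatientTermMatrix(fx$events, fx$labels, vocab = colnames(counts))
}

# random 2x2 tables with all margins positive
randomTables <- function(n, seed, max_cell = 80) {
  withr::with_seed(seed, {
    data.frame(A = sample.int(max_cell, n, TRUE),
               B = sample.int(max_cell, n, TRUE),
               C = sample.int(max_cell, n, TRUE),
               D = sample.int(max_cell, n, TRUE))
  })
}

tinySeparable <- function() goldenFixture("tiny_separable")
tinyImbalanced <- function() goldenFixture("tiny_imbalanced")
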