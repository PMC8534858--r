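# Phase 1: the bag-of-words patient representation and the stratified
# train/validation/test split.

#' Build the code vocabulary
#'
#' One entry per distinct code observed in the event table, in deterministic
#' lexicographic order (C locale).
#'
#' @param events event table from [readEvents()] or [generateCohort()].
#' @return character vector of distinct codes, sorted.
#' @export
buildVocabulary <- function(events) {
  if (is.null(events) || nrow(events) == 0L)
    pmStop("event table is empty", "empty_input_error")
  sort(unique(events$code), method = "radix")
}

#' Build the patient-term matrix
#'
#' Treats each patient as a document: entry (code, patient) is the number of
#' event rows for that pair — order and dates are ignored, only occurrence
#' counts matter. Patients appear in order of first appearance in the event
#' table; patients present in the label table but without any events are
#' appended as all-zero columns (legitimate "no recorded code" controls).
#'
#' @param events event table.
#' @param labels label table (`patient_id`, `outcome`); every event patient
#'   must be labelled.
#' @param vocab vocabulary; defaults to [buildVocabulary()] on `events`
#'   (full-dataset vocabulary). Pass a training-only vocabulary for a
#'   leakage-safe variant.
#' @param unknown_codes what to do with event codes absent from `vocab`:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @param dedup_daily if `TRUE`, collapse repeated identical
#'   (patient, code, date) rows before counting; default keeps all rows.
#' @return a [PatientTermMatrix-class].
#' @export
buildPatientTermMatrix <- function(events, labels, vocab = NULL,
                                   unknown_codes = c("drop", "error"),
                                   dedup_daily = FALSE) {
  unknown_codes <- match.arg(unknown_codes)
  if (is.null(vocab)) vocab <- buildVocabulary(events)
  if (dedup_daily && "date" %in% names(events))
    events <- events[!duplicated(events[, c("patient_id", "code", "date")]), ]

  unlabelled <- setdiff(unique(events$patient_id), labels$patient_id)
  if (length(unlabelled))
    pmStop(sprintf("event patient(s) without a label: %s",
                   paste(head(unlabelled, 5), collapse = ", ")),
           "integrity_error")

  unknown <- !(events$code %in% vocab)
  if (any(unknown)) {
    if (unknown_codes == "error")
      pmStop(sprintf("%d event row(s) carry codes absent from the vocabulary",
                     sum(unknown)), "lookup_error")
    warning(sprintf("dropping %d event row(s) with out-of-vocabulary codes",
                    sum(unknown)))
    events <- events[!unknown, , drop = FALSE]
  }

  patients <- unique(events$patient_id)                      # first appearance
  patients <- c(patients, setdiff(labels$patient_id, patients))
  ci <- match(events$code, vocab)
  pi <- match(events$patient_id, patients)
  counts <- Matrix::sparseMatrix(i = ci, j = pi, x = rep(1, length(ci)),
                                 dims = c(length(vocab), length(patients)),
                                 dimnames = list(vocab, patients))
  outcome <- labels$outcome[match(patients, labels$patient_id)]
  new("PatientTermMatrix", SummarizedExperiment(
    assays = list(counts = as(counts, "CsparseMatrix")),
    colData = DataFrame(outcome = as.integer(outcome), row.names = patients)))
}

#' Stratified train/validation/test split
#'
#' Assigns every patient to one part, stratified by outcome so that each
#' part's per-class size matches the requested fraction to within one
#' patient. Reproducible for a fixed seed.
#'
#' @param x a [PatientTermMatrix-class].
#' @param fractions named numeric of positive proportions summing to 1;
#'   default `c(train = 0.6, validation = 0.2, test = 0.2)`.
#' @param seed integer seed.
#' @return named factor (by patient id) of part assignments, with the
#'   fractions and seed attached as attributes.
#' @export
splitPatients <- function(x, fractions = c(train = 0.6, validation = 0.2,
                                           test = 0.2), seed = 1L) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    pmStop("fractions must be named", "config_error")
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    pmStop("fractions must be positive and sum to 1", "config_error")
  y <- outcomeLabels(x)
  for (cls in c(0L, 1L))
    if (sum(y == cls) < length(fractions))
      pmStop(sprintf("class %d has fewer members (%d) than parts (%d)",
                     cls, sum(y == cls), length(fractions)),
             "stratification_error")
  part <- stratifiedAssign(y, fractions, seed)
  out <- factor(setNames(part, patientIDs(x)), levels = names(fractions))
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- seed
  out
}

#' Subset a patient-term matrix to one split part
#'
#' @param x a [PatientTermMatrix-class].
#' @param plan assignment factor from [splitPatients()].
#' @param part part name, e.g. `"train"`.
#' @return the column-subset [PatientTermMatrix-class].
#' @export
splitPart <- function(x, plan, part) {
  if (!part %in% levels(plan)) pmStop(paste("unknown part:", part), "config_error")
  x[, names(plan)[plan == part]]
}
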