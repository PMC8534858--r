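# Reading and writing the external formats: long-format coded event tables,
# per-patient label tables, code dictionaries, ranked lists, reports, rules.
#
# Events and labels are plain UTF-8 CSV/TSV with a header. Default headers are
# patient_id,code,date,source; a `columns` mapping overrides them. Codes are
# opaque case-sensitive tokens (no terminology-hierarchy expansion).

.delim <- function(dialect) {
  dialect <- match.arg(dialect, c("csv", "tsv"))
  if (dialect == "csv") "," else "\t"
}

#' Read a long-format coded event table
#'
#' One row per recorded clinical event: a patient identifier and a code,
#' optionally an ISO-8601 date and a source tag. Duplicate (patient, code)
#' rows are meaningful — they become occurrence counts in the bag-of-words
#' representation. Row order is preserved.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param columns named list mapping the canonical names `patient_id`,
#'   `code`, `date`, `source` to the header names used in the file.
#' @return a `data.frame` with columns `patient_id`, `code` and, when present
#'   in the file, `date` and `source` (an event table).
#' @export
readEvents <- function(path, dialect = c("csv", "tsv"),
                       columns = list(patient_id = "patient_id", code = "code",
                                      date = "date", source = "source")) {
  if (!file.exists(path)) pmStop(paste("no such file:", path), "io_error")
  sep <- .delim(dialect)
  df <- read.csv(path, sep = sep, colClasses = "character",
                 check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) pmStop("event table is empty", "empty_input_error")
  for (fld in c("patient_id", "code")) {
    if (!columns[[fld]] %in% names(df))
      pmStop(sprintf("mandatory column '%s' missing", columns[[fld]]),
             "format_error")
  }
  out <- data.frame(patient_id = df[[columns$patient_id]],
                    code = df[[columns$code]],
                    stringsAsFactors = FALSE)
  if (!is.null(columns$date) && columns$date %in% names(df))
    out$date <- df[[columns$date]]
  if (!is.null(columns$source) && columns$source %in% names(df))
    out$source <- df[[columns$source]]
  if (any(!nzchar(out$patient_id)) || any(!nzchar(out$code)))
    pmStop("patient_id and code must be non-empty", "format_error")
  out
}

#' Read a gold-standard label table
#'
#' Two columns, patient identifier and binary outcome (1 = has the
#' condition). Consistent duplicate rows are tolerated; conflicting outcomes
#' for one patient are an integrity error.
#'
#' @inheritParams readEvents
#' @return a `data.frame` with columns `patient_id`, `outcome` (one row per
#'   patient; a label table).
#' @export
readLabels <- function(path, dialect = c("csv", "tsv"),
                       columns = list(patient_id = "patient_id",
                                      outcome = "outcome")) {
  if (!file.exists(path)) pmStop(paste("no such file:", path), "io_error")
  df <- read.csv(path, sep = .delim(dialect), colClasses = "character",
                 check.names = FALSE, fileEncoding = "UTF-8")
  for (fld in c("patient_id", "outcome")) {
    if (!columns[[fld]] %in% names(df))
      pmStop(sprintf("mandatory column '%s' missing", columns[[fld]]),
             "format_error")
  }
  pid <- df[[columns$patient_id]]
  out <- df[[columns$outcome]]
  if (!all(out %in% c("0", "1")))
    pmStop("outcome values must be 0 or 1", "format_error")
  out <- as.integer(out)
  agg <- tapply(out, pid, function(v) length(unique(v)))
  if (any(agg > 1L))
    pmStop(sprintf("conflicting outcomes for patient(s): %s",
                   paste(names(agg)[agg > 1L], collapse = ", ")),
           "integrity_error")
  keep <- !duplicated(pid)
  data.frame(patient_id = pid[keep], outcome = out[keep],
             stringsAsFactors = FALSE)
}

#' Read a code dictionary
#'
#' Maps code identifiers to free-text descriptions, used only to annotate
#' exported decision rules.
#'
#' @inheritParams readEvents
#' @return named character vector: description by code.
#' @export
readCodeDictionary <- function(path, dialect = c("csv", "tsv")) {
  if (!file.exists(path)) pmStop(paste("no such file:", path), "io_error")
  df <- read.csv(path, sep = .delim(dialect), colClasses = "character",
                 check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) pmStop("dictionary needs code and description columns",
                            "format_error")
  if (anyDuplicated(df[[1L]])) pmStop("duplicate codes in dictionary",
                                      "integrity_error")
  setNames(df[[2L]], df[[1L]])
}

.checkWritable <- function(path) {
  if (!dir.exists(dirname(path)))
    pmStop(paste("directory does not exist:", dirname(path)), "io_error")
}

#' Serialize / reload a performance report
#'
#' Reports round-trip through JSON carrying the four confusion counts and the
#' six metrics (NA metrics serialized as null).
#'
#' @param report a [PerformanceReport-class].
#' @param path destination / source file.
#' @return `readReport()` returns the reconstructed [PerformanceReport-class].
#' @export
writeReport <- function(report, path) {
  .checkWritable(path)
  jsonlite::write_json(list(confusion = as.list(report@confusion),
                            metrics = as.list(report@metrics)),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  if (!file.exists(path)) pmStop(paste("no such file:", path), "io_error")
  x <- jsonlite::read_json(path)
  toNum <- function(l) vapply(l, function(v) if (is.null(v)) NA_real_ else
    as.numeric(v), numeric(1))
  new("PerformanceReport", confusion = toNum(x$confusion),
      metrics = toNum(x$metrics))
}

#' Serialize / reload a ranked feature list as TSV
#'
#' Columns rank, code, score, method; scores written with full precision so
#' the reload is bit-exact.
#'
#' @param ranked a [RankedFeatures-class].
#' @param path destination / source file.
#' @export
writeRankedFeatures <- function(ranked, path) {
  .checkWritable(path)
  df <- ranked@ranking
  df$score <- sprintf("%.17g", df$score)
  df$method <- ranked@method
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRankedFeatures
#' @export
readRankedFeatures <- function(path) {
  if (!file.exists(path)) pmStop(paste("no such file:", path), "io_error")
  df <- read.delim(path, colClasses = c(rank = "integer", code = "character",
                                        score = "numeric", method = "character"))
  new("RankedFeatures", method = df$method[1L],
      ranking = df[, c("rank", "code", "score")])
}

#' Persist a patient-term matrix as MatrixMarket plus sidecars
#'
#' Writes `<stem>.mtx` (sparse counts, codes x patients), `<stem>.codes.txt`,
#' `<stem>.patients.txt` and `<stem>.labels.txt`. `readMatrixMM()` restores
#' the [PatientTermMatrix-class] exactly.
#'
#' @param x a [PatientTermMatrix-class].
#' @param stem path stem without extension.
#' @export
writeMatrixMM <- function(x, stem) {
  .checkWritable(paste0(stem, ".mtx"))
  Matrix::writeMM(termCounts(x), paste0(stem, ".mtx"))
  writeLines(codeIDs(x), paste0(stem, ".codes.txt"))
  writeLines(patientIDs(x), paste0(stem, ".patients.txt"))
  writeLines(as.character(outcomeLabels(x)), paste0(stem, ".labels.txt"))
  invisible(stem)
}

#' @rdname writeMatrixMM
#' @export
readMatrixMM <- function(stem) {
  m <- as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  codes <- readLines(paste0(stem, ".codes.txt"))
  patients <- readLines(paste0(stem, ".patients.txt"))
  labels <- as.integer(readLines(paste0(stem, ".labels.txt")))
  dimnames(m) <- list(codes, patients)
  new("PatientTermMatrix", SummarizedExperiment(
    assays = list(counts = m),
    colData = DataFrame(outcome = labels, row.names = patients)))
}

#' Write decision rules as plain text
#'
#' One rule per line in the form
#' `IF N100. > 0 AND F440. > 0 THEN 1 (support=23, confidence=0.88)`.
#'
#' @param rules rule `data.frame` from [exportRules()].
#' @param path destination file.
#' @export
writeRules <- function(rules, path) {
  .checkWritable(path)
  writeLines(rules$text, path)
  invisible(path)
}
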