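# Synthetic imbalanced coded-EHR cohorts with planted informative codes, so
# every pipeline stage is testable without access-restricted clinical data.
#
# Generative model: outcome ~ Bernoulli(prevalence); events per patient ~
# Poisson(mean_events); each event's code drawn from a categorical whose
# background weights follow a Zipf law rank^(-s). A planted informative code
# replaces its Zipf weight with base_rate (its per-event probability in
# negatives), multiplied by rate_ratio in positives, the remaining mass being
# renormalized — so the count structure itself, not just presence, carries
# the signal.

#' Cohort generator configuration
#'
#' @param n_patients cohort size.
#' @param prevalence positive-outcome probability, in (0, 1).
#' @param n_codes distinct background codes.
#' @param zipf_exponent Zipf slope `s > 0` of background code popularity.
#' @param mean_events Poisson mean of events per patient.
#' @param informative `data.frame` with columns `index` (code index, distinct,
#'   `<= n_codes`), `rate_ratio` (`>= 1`) and `base_rate` (per-event
#'   probability in negatives); may be empty.
#' @param seed integer seed for the single cohort random stream.
#' @return validated configuration list of class `CohortConfig`.
#' @export
cohortConfig <- function(n_patients, prevalence, n_codes,
                         zipf_exponent = 1.2, mean_events = 20,
                         informative = NULL, seed = 1L) {
  if (n_patients < 1 || n_codes < 1)
    pmStop("n_patients and n_codes must be >= 1", "config_error")
  if (prevalence <= 0 || prevalence >= 1)
    pmStop("prevalence must lie in (0, 1)", "config_error")
  if (zipf_exponent <= 0 || mean_events <= 0)
    pmStop("zipf_exponent and mean_events must be > 0", "config_error")
  if (is.null(informative))
    informative <- data.frame(index = integer(), rate_ratio = numeric(),
                              base_rate = numeric())
  stopifnot(all(c("index", "rate_ratio", "base_rate") %in% names(informative)))
  if (anyDuplicated(informative$index) ||
      any(informative$index < 1 | informative$index > n_codes))
    pmStop("informative indices must be distinct and within 1..n_codes",
           "config_error")
  if (any(informative$rate_ratio < 1))
    pmStop("rate_ratio must be >= 1", "config_error")
  if (sum(informative$base_rate * informative$rate_ratio) >= 1 ||
      any(informative$base_rate <= 0))
    pmStop("informative base rates (times rate ratios) must stay below 1",
           "config_error")
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence, n_codes = as.integer(n_codes),
                 zipf_exponent = zipf_exponent, mean_events = mean_events,
                 informative = informative, seed = as.integer(seed)),
            class = "CohortConfig")
}

.codeLabels <- function(n) paste0("Z", formatC(seq_len(n), width = 4, flag = "0"))

.eventProbs <- function(cfg, positive) {
  w <- seq_len(cfg$n_codes)^(-cfg$zipf_exponent)
  inf <- cfg$informative
  if (nrow(inf)) {
    p_inf <- inf$base_rate * (if (positive) inf$rate_ratio else 1)
    w[inf$index] <- 0
    w <- w / sum(w) * (1 - sum(p_inf))
    w[inf$index] <- p_inf
  } else {
    w <- w / sum(w)
  }
  w
}

#' Generate a synthetic coded-EHR cohort
#'
#' Draws labels first, then per-patient event counts, then event codes, all
#' from one seeded stream: byte-identical output for a fixed configuration.
#'
#' @param cfg a `CohortConfig` from [cohortConfig()].
#' @param code_labels optional character vector of length `n_codes` naming
#'   the codes (default `Z0001..`); lets fixtures plant recognizable codes.
#' @return list with `events` (long-format event table) and `labels`
#'   (patient/outcome table).
#' @export
generateCohort <- function(cfg, code_labels = NULL) {
  if (!inherits(cfg, "CohortConfig")) pmStop("cfg must come from cohortConfig()",
                                             "config_error")
  if (is.null(code_labels)) code_labels <- .codeLabels(cfg$n_codes)
  if (length(code_labels) != cfg$n_codes || anyDuplicated(code_labels))
    pmStop("code_labels must be n_codes distinct names", "config_error")
  pids <- paste0("P", formatC(seq_len(cfg$n_patients), width = 5, flag = "0"))
  p_neg <- .eventProbs(cfg, positive = FALSE)
  p_pos <- .eventProbs(cfg, positive = TRUE)
  withSeed(cfg$seed, {
    y <- rbinom(cfg$n_patients, 1L, cfg$prevalence)
    n_ev <- rpois(cfg$n_patients, cfg$mean_events)
    codes_neg <- sample.int(cfg$n_codes, sum(n_ev[y == 0]), replace = TRUE,
                            prob = p_neg)
    codes_pos <- sample.int(cfg$n_codes, sum(n_ev[y == 1]), replace = TRUE,
                            prob = p_pos)
  })
  patient <- c(rep(pids[y == 0], n_ev[y == 0]), rep(pids[y == 1], n_ev[y == 1]))
  code_ix <- c(codes_neg, codes_pos)
  events <- data.frame(patient_id = patient, code = code_labels[code_ix],
                       stringsAsFactors = FALSE)
  events <- events[order(match(events$patient_id, pids)), , drop = FALSE]
  rownames(events) <- NULL
  list(events = events,
       labels = data.frame(patient_id = pids, outcome = y,
                           stringsAsFactors = FALSE))
}

#' Deterministic benchmark cohorts
#'
#' Four named cohorts used across the test-suite and examples:
#' `tiny_separable` (12 patients, one code that equals the outcome),
#' `tiny_imbalanced` (50 patients, 2 positives sharing a partially specific
#' code — exercises cost-sensitive leaf labelling), `as_like` (2000 patients,
#' 2% prevalence, two planted codes named `N100.` and `F440.` at rate ratio
#' 8, mirroring a low-prevalence spondyloarthritis cohort) and `ra_like`
#' (2000 patients, 14% prevalence, ten planted codes). The tiny cohorts ship
#' as CSVs under `inst/extdata`; the large ones are regenerated
#' deterministically from fixed seeds.
#'
#' @param name one of `"tiny_separable"`, `"tiny_imbalanced"`, `"as_like"`,
#'   `"ra_like"`.
#' @return list with `events` and `labels` tables.
#' @export
goldenFixture <- function(name = c("tiny_separable", "tiny_imbalanced",
                                   "as_like", "ra_like")) {
  name <- match.arg(name)
  extdata <- function(f) system.file("extdata", f, package = "PhenoMiner",
                                     mustWork = TRUE)
  if (name %in% c("tiny_separable", "tiny_imbalanced")) {
    return(list(events = readEvents(extdata(paste0(name, "_events.csv"))),
                labels = readLabels(extdata(paste0(name, "_labels.csv")))))
  }
  if (name == "as_like") {
    cfg <- cohortConfig(n_patients = 2000, prevalence = 0.02, n_codes = 500,
                        zipf_exponent = 1.2, mean_events = 20,
                        informative = data.frame(index = c(101L, 102L),
                                                 rate_ratio = c(8, 8),
                                                 base_rate = c(0.01, 0.01)),
                        seed = 20210L)
    labels <- .codeLabels(cfg$n_codes)
    labels[c(101L, 102L)] <- c("N100.", "F440.")
    return(generateCohort(cfg, code_labels = labels))
  }
  cfg <- cohortConfig(n_patients = 2000, prevalence = 0.14, n_codes = 500,
                      zipf_exponent = 1.2, mean_events = 20,
                      informative = data.frame(index = 101:110,
                                               rate_ratio = rep(6, 10),
                                               base_rate = rep(0.008, 10)),
                      seed = 20211L)
  generateCohort(cfg)
}
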