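# End-to-end orchestration: representation -> ranking + forward selection ->
# grid-searched trees -> final model, with every artifact written to disk.
# Driven by a YAML (or list) configuration validated before any compute.

.configSchema <- list(
  events = "character", labels = "character", dictionary = "character",
  output_dir = "character",
  split = list(fractions = "list", seed = "numeric"),
  ranking = list(methods = "character"),
  selection = list(i_max = "numeric", tolerance = "numeric"),
  grids = list(profiles = "character", folds = "numeric", seed = "numeric",
               axes = "list"),
  learner = list(min_split = "numeric", min_child = "numeric"))

.validateConfig <- function(cfg) {
  unknown <- setdiff(names(cfg), names(.configSchema))
  if (length(unknown))
    pmStop(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
           "config_error")
  for (nm in intersect(names(cfg), names(.configSchema))) {
    sub <- .configSchema[[nm]]
    if (is.list(sub)) {
      bad <- setdiff(names(cfg[[nm]]), names(sub))
      if (length(bad))
        pmStop(sprintf("unknown config key(s) under %s: %s", nm,
                       paste(bad, collapse = ", ")), "config_error")
    }
  }
  for (req in c("events", "labels", "output_dir"))
    if (is.null(cfg[[req]]))
      pmStop(paste("config key required:", req), "config_error")
  fr <- cfg$split$fractions
  if (!is.null(fr) && abs(sum(unlist(fr)) - 1) > 1e-9)
    pmStop("split fractions must sum to 1", "config_error")
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    pmStop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           "pipeline_error")
  })
}

# atomic artifact write: a crash mid-write leaves only a .partial file
.artifact <- function(path, writer) {
  tmp <- paste0(path, ".partial")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full phenotyping pipeline
#'
#' Executes the three phases — patient representation, ranking plus forward
#' selection per requested index, and cross-validated grid search with final
#' model selection — and writes every intermediate artifact (matrix, ranked
#' lists, selection traces, grid tables, final model JSON, rules text and the
#' test-set report) under `output_dir`. Re-running with an unchanged
#' configuration reproduces the artifacts.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Recognized keys: `events`, `labels`, `dictionary` (paths),
#'   `output_dir`, `split` (`fractions`, `seed`), `ranking` (`methods`),
#'   `selection` (`i_max`, `tolerance`), `grids` (`profiles`, `folds`,
#'   `seed`, `axes`), `learner` (`min_split`, `min_child`). Unknown keys are
#'   rejected before any compute.
#' @return (invisibly) a list with the final `model`, test `report`, per
#'   method `traces` and the artifact directory.
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- .validateConfig(cfg)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  events <- .stage("read", readEvents(cfg$events))
  labels <- .stage("read", readLabels(cfg$labels))
  dict <- if (!is.null(cfg$dictionary))
    .stage("read", readCodeDictionary(cfg$dictionary)) else NULL

  ptm <- .stage("represent", buildPatientTermMatrix(events, labels))
  message(sprintf("[represent] %d codes x %d patients", nrow(ptm), ncol(ptm)))
  .artifact(file.path(out, "matrix.mtx"), function(tmp) {
    stem <- sub("\\.mtx\\.partial$", "", tmp)
    writeMatrixMM(ptm, stem)
    file.rename(paste0(stem, ".mtx"), tmp)
  })

  fractions <- if (!is.null(cfg$split$fractions))
    unlist(cfg$split$fractions) else c(train = 0.6, validation = 0.2, test = 0.2)
  seed <- if (!is.null(cfg$split$seed)) as.integer(cfg$split$seed) else 1L
  plan <- .stage("split", splitPatients(ptm, fractions, seed))
  train <- splitPart(ptm, plan, "train")
  val <- splitPart(ptm, plan, "validation")
  test <- splitPart(ptm, plan, "test")

  methods <- cfg$ranking$methods
  if (is.null(methods)) methods <- c("chi2", "info_gain", "dkm", "binomial")
  i_max <- if (!is.null(cfg$selection$i_max)) cfg$selection$i_max else 400L
  tol <- if (!is.null(cfg$selection$tolerance)) cfg$selection$tolerance else 0
  ms <- if (!is.null(cfg$learner$min_split)) cfg$learner$min_split else 20
  mc <- if (!is.null(cfg$learner$min_child)) cfg$learner$min_child else 7
  learner <- function(tr, feats)
    fitTree(tr, feats, treeParams(profile = "c50", min_split = ms,
                                  min_child = mc, fn_cost = 1))

  traces <- list()
  subsets <- list()
  for (m in methods) {
    ranked <- .stage("rank", rankFeatures(ptm, m, subset = patientIDs(train)))
    .artifact(file.path(out, sprintf("ranked_%s.tsv", m)),
              function(tmp) writeRankedFeatures(ranked, tmp))
    trace <- .stage("select", forwardSelect(ranked, train, val,
                                            learner = learner,
                                            i_max = i_max, tolerance = tol))
    stopifnot(fitCount(trace) <= i_max)
    traces[[m]] <- trace
    message(sprintf("[select %s] best cut-off %d, second %s (%d fits)",
                    m, bestCutoff(trace),
                    ifelse(is.na(secondCutoff(trace)), "NA",
                           secondCutoff(trace)), fitCount(trace)))
    .artifact(file.path(out, sprintf("trace_%s.tsv", m)), function(tmp)
      write.table(selectionSteps(trace), tmp, sep = "\t", quote = FALSE,
                  row.names = FALSE))
    .artifact(file.path(out, sprintf("selection_%s.json", m)), function(tmp)
      jsonlite::write_json(list(method = m, best_cutoff = bestCutoff(trace),
                                second_cutoff = secondCutoff(trace),
                                tolerance = tol, n_fits = fitCount(trace)),
                           tmp, auto_unbox = TRUE, digits = NA, na = "null"))
    fs <- featureSubsets(trace, ranked)
    for (which in names(fs))
      subsets[[sprintf("%s_%s", m, which)]] <- fs[[which]]
  }

  profiles <- cfg$grids$profiles
  if (is.null(profiles)) profiles <- "c50"
  folds <- if (!is.null(cfg$grids$folds)) as.integer(cfg$grids$folds) else 10L
  gseed <- if (!is.null(cfg$grids$seed)) as.integer(cfg$grids$seed) else seed
  candidates <- list()
  for (sn in names(subsets)) {
    for (pf in profiles) {
      axes <- cfg$grids$axes[[pf]]
      gr <- .stage("gridsearch", crossValidatedGridSearch(
        train, subsets[[sn]], profile = pf, grid = axes, folds = folds,
        seed = gseed, base = list(min_split = ms, min_child = mc)))
      message(sprintf("[gridsearch %s %s] best cv agreement %.4f", sn, pf,
                      max(gr@table$cv_agreement)))
      .artifact(file.path(out, sprintf("grid_%s_%s.tsv", pf, sn)),
                function(tmp) write.table(gr@table, tmp, sep = "\t",
                                          quote = FALSE, row.names = FALSE))
      candidates[[sprintf("%s_%s", sn, pf)]] <-
        list(features = subsets[[sn]], profile = pf, params = gr@best)
    }
  }

  final <- .stage("evaluate", selectFinalModel(candidates, train, val, test,
                                               base = list(min_split = ms,
                                                           min_child = mc)))
  message(sprintf("[evaluate] winner %s, test accuracy %.4f",
                  names(candidates)[final$winner],
                  metrics(final$report)["accuracy"]))
  .artifact(file.path(out, "final_model.json"),
            function(tmp) writeTreeModel(final$model, tmp))
  .artifact(file.path(out, "rules.txt"),
            function(tmp) writeRules(exportRules(final$model, dict), tmp))
  .artifact(file.path(out, "report.json"),
            function(tmp) writeReport(final$report, tmp))
  .artifact(file.path(out, "run_info.json"), function(tmp) {
    cfgfile <- file.path(out, "config_used.yaml")
    yaml::write_yaml(cfg, cfgfile)
    jsonlite::write_json(list(config_md5 = unname(tools::md5sum(cfgfile)),
                              split_seed = seed, grid_seed = gseed),
                         tmp, auto_unbox = TRUE)
  })
  invisible(list(model = final$model, report = final$report, traces = traces,
                 winner = names(candidates)[final$winner], output_dir = out))
}
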