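#' Run the simulate–detect–evaluate pipeline
#'
#' Composes the full surveillance loop into one reproducible run: simulate a
#' cohort from the configured plan, run the rule set over every record,
#' match and classify alarms against the truth log, and write all
#' intermediate CSVs plus a metrics report and a JSON manifest (seed,
#' configuration, package version) into `out`.
#'
#' @param config a configuration list, or the path to a YAML file with the
#'   same structure. Recognized fields:
#'   \describe{
#'     \item{cohort}{`n_patients`, `duration_s`, `plan` (list of
#'       `kind`/`count`/`margin` entries).}
#'     \item{rules}{path to a YAML rule file; omitted = the five built-in
#'       scenarios.}
#'     \item{engine}{`co_occurrence_s`, `refractory_s` (omitted = per-rule
#'       values), `compatibility_mode` (logical), `plausibility` (map
#'       channel -> `[low, high]`), `tolerance_s` (matching tolerance).}
#'     \item{seed}{integer; overridden by the `seed` argument if given.}
#'   }
#' @param out output directory (created if needed).
#' @param seed optional integer overriding `config$seed`.
#' @param writeRecords logical; write per-patient record CSVs (large; off
#'   by default).
#' @return Invisibly, a list with `records`, `truth`, `alarms`,
#'   `eligibility`, `classifications`, `summary`, and `manifest`.
#' @export
runPipeline <- function(config = list(), out = tempfile("icualarms_run_"),
                        seed = NULL, writeRecords = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) config$seed <- 1L
  cohort <- config$cohort %||% list()
  plan <- if (is.null(cohort$plan)) {
    data.frame(kind = character(0), count = integer(0), margin = numeric(0))
  } else {
    do.call(rbind, lapply(cohort$plan, function(p)
      data.frame(kind = p$kind, count = p$count, margin = p$margin,
                 stringsAsFactors = FALSE)))
  }
  spec <- cohortSpec(nPatients = cohort$n_patients %||% 10,
                     duration = cohort$duration_s %||% 86400,
                     plan = plan, seed = config$seed)
  rules <- if (is.null(config$rules)) builtinScenarios()
           else loadRules(path = config$rules)
  engine <- config$engine %||% list()
  plaus <- if (!is.null(engine$plausibility))
    lapply(engine$plausibility, as.numeric) else NULL
  det_args <- list(rules = rules,
                   compatibilityMode = isTRUE(engine$compatibility_mode),
                   plausibility = plaus)
  if (!is.null(engine$co_occurrence_s))
    det_args$coOccurrence <- engine$co_occurrence_s
  if (!is.null(engine$refractory_s))
    det_args$refractory <- engine$refractory_s
  tolerance <- engine$tolerance_s %||% 60

  sim <- simulateCohort(spec)
  det <- do.call(detectAlarms, c(list(records = sim$records), det_args))
  matches <- matchAlarms(det$alarms, sim$truth, tolerance = tolerance)
  cls <- classifyEvents(matches)
  scen <- vapply(rules, ruleName, "")
  rows <- do.call(rbind, lapply(scen, function(s) computeMetrics(cls, s)))
  summ <- summarizeCohort(rows, alarms = det$alarms, truth = sim$truth,
                          records = sim$records)

  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (writeRecords) {
    rec_dir <- file.path(out, "records")
    dir.create(rec_dir, showWarnings = FALSE)
    for (r in sim$records)
      writeRecordCSV(r, file.path(rec_dir, paste0(r@patientId, ".csv")))
  }
  writeTruthLog(sim$truth, file.path(out, "truth.csv"))
  writeAlarmLog(det$alarms, file.path(out, "alarms.csv"))
  utils::write.csv(det$eligibility, file.path(out, "eligibility.csv"),
                   row.names = FALSE)
  writeClassificationLog(cls, file.path(out, "classifications.csv"))
  writeMetricsReport(summ, file.path(out, "metrics.csv"))
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("icualarms")),
    n_patients = spec@nPatients, duration_s = spec@duration,
    compatibility_mode = isTRUE(engine$compatibility_mode),
    plausibility = engine$plausibility, tolerance_s = tolerance,
    rules = vapply(rules, ruleName, ""),
    config = config)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(records = sim$records, truth = sim$truth,
                 alarms = det$alarms, eligibility = det$eligibility,
                 classifications = cls, summary = summ,
                 manifest = manifest, out = out))
}
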