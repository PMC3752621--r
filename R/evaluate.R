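# Evaluation layer: interval matching of alarms against ground truth, the
# eight-label event-classification taxonomy, and per-scenario metrics
# (counts and positive predictive value).

.EVENT_LABELS <- c("TPRE", "TP_PREDICT", "FP_ART", "FP_INS_DEF",
                   "FN_TH", "FN_NO_TH", "FN_SENS_OFF", "TN_TIME_INT")

.isClinicalKind <- function(kind) kind %in% .episodeKinds()
.isArtifactKind <- function(kind) {
  startsWith(kind, "artifact_") | kind == "sensor_off"
}

#' Match alarms to ground-truth events
#'
#' An alarm matches a clinical truth event when it comes from the event's
#' own scenario, the same patient, and fires within
#' `[t_start - tolerance, t_end + tolerance]`. Artifact truth events absorb
#' alarms of any scenario in their interval (an artifact does not care which
#' definition it fooled), as do explicit `confounder` truth labels (the
#' hook for "insufficient definition" false positives, e.g. a patient on an
#' assist device). Matching is greedy earliest-first and one-to-many: one
#' truth event may absorb several refractory-separated alarms. Clinical
#' matches take precedence over artifact matches when intervals overlap.
#'
#' @param alarms alarm data.frame (from [detectAlarms()]).
#' @param truth truth data.frame (from [simulateCohort()] or
#'   [readTruthLog()]).
#' @param tolerance matching tolerance in seconds (default 60, one monitor
#'   trend-screen unit; the study's daily-review adjudication had no finer
#'   granularity).
#' @return List with `alarms` (input plus `truth_row`, `truth_kind`
#'   columns) and `truth` (input plus `matched`, `n_alarms` columns).
#' @export
matchAlarms <- function(alarms, truth, tolerance = 60) {
  alarms <- alarms[order(alarms$patient_id, alarms$t_fire,
                         alarms$scenario), , drop = FALSE]
  rownames(alarms) <- NULL
  alarms$truth_row <- rep(NA_integer_, nrow(alarms))
  alarms$truth_kind <- rep(NA_character_, nrow(alarms))
  truth$matched <- logical(nrow(truth))
  truth$n_alarms <- integer(nrow(truth))
  if (nrow(alarms) && nrow(truth)) {
    for (i in seq_len(nrow(alarms))) {
      a <- alarms[i, ]
      same_pat <- truth$patient_id == a$patient_id
      in_win <- same_pat &
        a$t_fire >= truth$t_start - tolerance &
        a$t_fire <= truth$t_end + tolerance
      clin <- in_win & .isClinicalKind(truth$kind) &
        scenarioForKind(truth$kind) == a$scenario
      cand <- which(clin)
      if (!length(cand)) cand <- which(in_win & .isArtifactKind(truth$kind))
      if (!length(cand)) cand <- which(in_win & truth$kind == "confounder")
      if (length(cand)) {
        j <- cand[order(truth$t_start[cand])][1]
        alarms$truth_row[i] <- j
        alarms$truth_kind[i] <- truth$kind[j]
        truth$matched[j] <- TRUE
        truth$n_alarms[j] <- truth$n_alarms[j] + 1L
      }
    }
  }
  list(alarms = alarms, truth = truth)
}

#' Classify every alarm and truth event
#'
#' Applies the event-classification taxonomy:
#' * `TPRE` — alarm(s) matched to a real clinical episode, first alarm at
#'   or after onset;
#' * `TP_PREDICT` — matched alarm(s) strictly before episode onset (within
#'   tolerance);
#' * `FP_ART` — alarm matched to an artifact truth event (e.g. a CVP of
#'   200 mmHg), or an alarm with no ground-truth correlate;
#' * `FP_INS_DEF` — alarm co-occurring with an explicit `confounder` truth
#'   label (the definition is insufficient for that clinical context);
#' * `FN_SENS_OFF` — detectable episode missed while a required sensor was
#'   disconnected;
#' * `FN_TH` — detectable episode missed with sensors on (definition
#'   failure);
#' * `FN_NO_TH` — sub-threshold episode that (correctly) produced no alarm.
#'
#' By default multiple alarms inside one truth interval count as a single
#' event (alarms repeat on re-arming; the taxonomy counts events); set
#' `alarmCounting = "alarms"` to count each alarm separately.
#'
#' @param matches output of [matchAlarms()].
#' @param alarmCounting `"events"` (default) or `"alarms"`.
#' @return A classification log data.frame: `patient_id`, `scenario`,
#'   `label`, `t`, `truth_kind`, `n_alarms`, `rationale`.
#' @export
classifyEvents <- function(matches, alarmCounting = c("events", "alarms")) {
  alarmCounting <- match.arg(alarmCounting)
  alarms <- matches$alarms
  truth <- matches$truth
  rows <- list()
  emit <- function(patient_id, scenario, label, t, truth_kind, n_alarms,
                   rationale) {
    rows[[length(rows) + 1L]] <<- data.frame(
      patient_id = patient_id, scenario = scenario, label = label, t = t,
      truth_kind = truth_kind, n_alarms = n_alarms, rationale = rationale,
      stringsAsFactors = FALSE)
  }
  matched_idx <- which(!is.na(alarms$truth_row))
  by_truth <- split(matched_idx, alarms$truth_row[matched_idx])
  for (js in names(by_truth)) {
    j <- as.integer(js)
    tr <- truth[j, ]
    aset <- alarms[by_truth[[js]], , drop = FALSE]
    if (.isClinicalKind(tr$kind)) {
      if (alarmCounting == "alarms") {
        for (r in seq_len(nrow(aset))) {
          lbl <- if (aset$t_fire[r] >= tr$t_start) "TPRE" else "TP_PREDICT"
          emit(tr$patient_id, aset$scenario[r], lbl, aset$t_fire[r],
               tr$kind, 1L, "alarm matched clinical episode")
        }
      } else {
        lbl <- if (any(aset$t_fire >= tr$t_start)) "TPRE" else "TP_PREDICT"
        emit(tr$patient_id, scenarioForKind(tr$kind), lbl,
             min(aset$t_fire), tr$kind, nrow(aset),
             "alarm(s) matched clinical episode")
      }
    } else if (.isArtifactKind(tr$kind)) {
      for (sc in unique(aset$scenario)) {
        sub <- aset[aset$scenario == sc, , drop = FALSE]
        n_ev <- if (alarmCounting == "alarms") nrow(sub) else 1L
        for (e in seq_len(n_ev))
          emit(tr$patient_id, sc, "FP_ART", min(sub$t_fire), tr$kind,
               if (alarmCounting == "alarms") 1L else nrow(sub),
               "alarm matched artifact episode")
      }
    } else {                                    # confounder
      for (sc in unique(aset$scenario)) {
        sub <- aset[aset$scenario == sc, , drop = FALSE]
        n_ev <- if (alarmCounting == "alarms") nrow(sub) else 1L
        for (e in seq_len(n_ev))
          emit(tr$patient_id, sc, "FP_INS_DEF", min(sub$t_fire), tr$kind,
               if (alarmCounting == "alarms") 1L else nrow(sub),
               "alarm co-occurred with confounder label")
      }
    }
  }
  unmatched <- which(is.na(alarms$truth_row))
  for (i in unmatched) {
    emit(alarms$patient_id[i], alarms$scenario[i], "FP_ART",
         alarms$t_fire[i], NA_character_, 1L,
         "no ground-truth correlate (noise- or artifact-triggered)")
  }
  clin_un <- which(!truth$matched & .isClinicalKind(truth$kind))
  for (j in clin_un) {
    tr <- truth[j, ]
    sc <- scenarioForKind(tr$kind)
    if (!tr$intended_detectable) {
      emit(tr$patient_id, sc, "FN_NO_TH", tr$t_start, tr$kind, 0L,
           "sub-threshold episode, correctly no alarm")
    } else {
      so <- truth$kind == "sensor_off" &
        truth$patient_id == tr$patient_id &
        truth$t_start < tr$t_end & truth$t_end > tr$t_start
      if (any(so)) {
        emit(tr$patient_id, sc, "FN_SENS_OFF", tr$t_start, tr$kind, 0L,
             "detectable episode overlapped a sensor-off interval")
      } else {
        emit(tr$patient_id, sc, "FN_TH", tr$t_start, tr$kind, 0L,
             "detectable episode missed (definition failure)")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(patient_id = character(0), scenario = character(0),
                         label = character(0), t = numeric(0),
                         truth_kind = character(0), n_alarms = integer(0),
                         rationale = character(0))
  out <- out[order(out$patient_id, out$t, out$scenario), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-scenario metrics row
#'
#' Counts alarm-side events and misses for one scenario and computes the
#' positive predictive value
#' `PPV = (TPRE + TP_PREDICT) / (TPRE + TP_PREDICT + FP_ART + FP_INS_DEF)`;
#' `NA` when the scenario produced no alarms.
#'
#' @param classifications classification log from [classifyEvents()].
#' @param scenario scenario name.
#' @return One-row data.frame: `scenario`, `n_events`, `tp`, `fp_art`,
#'   `fp_ins_def`, `ppv`, `fn`.
#' @export
computeMetrics <- function(classifications, scenario) {
  cl <- classifications[classifications$scenario == scenario, , drop = FALSE]
  tp <- sum(cl$label %in% c("TPRE", "TP_PREDICT"))
  fp_art <- sum(cl$label == "FP_ART")
  fp_ins_def <- sum(cl$label == "FP_INS_DEF")
  fn <- sum(cl$label %in% c("FN_TH", "FN_NO_TH", "FN_SENS_OFF"))
  metricsFromCounts(scenario, tp, fp_art, fp_ins_def, fn)
}

#' Metrics row from raw counts
#'
#' Builds the same row as [computeMetrics()] directly from event counts —
#' e.g. the counts printed in a study report — so PPV arithmetic can be
#' verified independently of the detection pipeline.
#'
#' @param scenario scenario name.
#' @param tp true-positive events (real + predictive).
#' @param fpArt false positives caused by artifact.
#' @param fpInsDef false positives from insufficient definitions.
#' @param fn false negatives (all flavours).
#' @return One-row data.frame: `scenario`, `n_events`, `tp`, `fp_art`,
#'   `fp_ins_def`, `ppv`, `fn`.
#' @examples
#' metricsFromCounts("LV shock", tp = 34, fpArt = 8)$ppv  # 34/42
#' @export
metricsFromCounts <- function(scenario, tp, fpArt, fpInsDef = 0, fn = 0) {
  n_events <- tp + fpArt + fpInsDef
  ppv <- if (n_events > 0) tp / n_events else NA_real_
  data.frame(scenario = scenario, n_events = n_events, tp = tp,
             fp_art = fpArt, fp_ins_def = fpInsDef, ppv = ppv, fn = fn,
             stringsAsFactors = FALSE)
}

#' Cohort-level summary table
#'
#' Stacks per-scenario metrics rows into a report table (scenario, number
#' of events, TP, FP artifact, FP insufficient definition, PPV, FN) and
#' computes the overall false-positive fraction
#' `sum(fp_art + fp_ins_def) / sum(n_events)` across scenarios. When
#' `alarms`, `truth` and `records` are supplied, also counts quiet
#' time intervals (`TN_TIME_INT`) per scenario: patient-days with neither
#' an alarm nor a truth event of that scenario.
#'
#' @param rows list (or data.frame) of metrics rows from
#'   [computeMetrics()] / [metricsFromCounts()].
#' @param alarms,truth,records optional, for time-interval accounting.
#' @return List with `table` (data.frame), `overall_fp_fraction`, and — if
#'   computable — `patient_days` and a `tn_time_int` column in the table.
#' @export
summarizeCohort <- function(rows, alarms = NULL, truth = NULL,
                            records = NULL) {
  tab <- if (is.data.frame(rows)) rows else do.call(rbind, rows)
  rownames(tab) <- NULL
  total_events <- sum(tab$n_events)
  overall_fp <- if (total_events > 0)
    sum(tab$fp_art + tab$fp_ins_def) / total_events else NA_real_
  out <- list(table = tab, overall_fp_fraction = overall_fp)
  if (!is.null(records) && !is.null(alarms) && !is.null(truth)) {
    day <- 86400
    pat_days <- sum(vapply(records, function(r)
      ceiling(r@duration / day), 0))
    tn <- integer(nrow(tab))
    for (k in seq_len(nrow(tab))) {
      sc <- tab$scenario[k]
      busy <- 0L
      for (r in records) {
        nd <- ceiling(r@duration / day)
        for (d in seq_len(nd)) {
          w0 <- (d - 1) * day; w1 <- d * day
          has_alarm <- any(alarms$scenario == sc &
                             alarms$patient_id == r@patientId &
                             alarms$t_fire >= w0 & alarms$t_fire < w1)
          has_truth <- any(truth$patient_id == r@patientId &
                             .isClinicalKind(truth$kind) &
                             scenarioForKind(truth$kind) == sc &
                             truth$t_start < w1 & truth$t_end > w0)
          if (has_alarm || has_truth) busy <- busy + 1L
        }
      }
      tn[k] <- pat_days - busy
    }
    out$table$tn_time_int <- tn
    out$patient_days <- pat_days
  }
  out
}

#' Write evaluation outputs
#'
#' `writeClassificationLog` writes the per-event classification log;
#' `writeMetricsReport` writes the summary table as CSV and, alongside it,
#' a plain-text rendering (same basename, `.txt`) with the overall
#' false-positive fraction.
#'
#' @param classifications classification log from [classifyEvents()].
#' @param summary output of [summarizeCohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeClassificationLog <- function(classifications, path) {
  utils::write.csv(classifications, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClassificationLog
#' @export
writeMetricsReport <- function(summary, path) {
  utils::write.csv(summary$table, path, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(summary$table,
                                         row.names = FALSE)), con)
  writeLines(sprintf("overall FP fraction: %.4f",
                     summary$overall_fp_fraction), con)
  if (!is.null(summary$patient_days))
    writeLines(sprintf("patient-days: %d",
                       as.integer(summary$patient_days)), con)
  invisible(path)
}
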