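# Scenario-level evaluation: eligibility, conjunction across trigger slots,
# refractory handling, and the cohort-level detection loop.

# Trigger slots of a rule: triggers whose channels share an eitherGroups
# entry form one slot (satisfied by any member); every other trigger is its
# own slot. Returns a list of integer vectors (trigger indices).
.ruleSlots <- function(rule) {
  ch <- vapply(rule@triggers, function(tr) tr@channel, "")
  slot_of <- seq_along(ch)
  for (g in rule@eitherGroups) {
    members <- which(ch %in% g)
    if (length(members) > 1L) slot_of[members] <- min(members)
  }
  unname(split(seq_along(ch), slot_of))
}

# The trace a trigger reads in a record: primary channel if present,
# otherwise the declared fallback; NULL if neither exists.
.resolveTrace <- function(record, spec) {
  tr <- getTrace(record, spec@channel)
  if (is.null(tr) && !is.na(spec@fallback))
    tr <- getTrace(record, spec@fallback)
  tr
}

.missingFraction <- function(record, channel, rate = 1, gapTolerance = 10) {
  tr <- getTrace(record, channel)
  if (is.null(tr)) return(1)
  grid <- seq(0, record@duration, by = 1 / rate)
  mean(is.na(.gridValues(tr, grid, gapTolerance)))
}

#' Check whether a record carries the sensors a rule requires
#'
#' A rule is eligible on a record when every trigger slot has at least one
#' usable source: the trigger's channel (or its declared fallback) exists in
#' the record with less than `maxMissing` missing data overall. Records
#' failing this check contribute no alarms and no events to evaluation,
#' mirroring the study rule that events were not analyzed when the requisite
#' sensors were absent.
#'
#' @param record a [PatientRecord-class].
#' @param rule a [ScenarioRule-class].
#' @param maxMissing maximum tolerated missing fraction (default 0.5).
#' @param rate,gapTolerance grid parameters for the missing-data check.
#' @return List with `eligible` (logical) and `missing` (character vector of
#'   channels that made slots fail; empty when eligible).
#' @examples
#' rec <- patientRecord("p1", 100, list(makeTrace("HR", 0:99, rep(80, 100))))
#' sensorsPresent(rec, builtinScenarios()[[3]])
#' @export
sensorsPresent <- function(record, rule, maxMissing = 0.5, rate = 1,
                           gapTolerance = 10) {
  usable <- function(channel) {
    !is.null(getTrace(record, channel)) &&
      .missingFraction(record, channel, rate, gapTolerance) < maxMissing
  }
  missing <- character(0)
  eligible <- TRUE
  for (slot in .ruleSlots(rule)) {
    slot_ok <- FALSE
    slot_missing <- character(0)
    for (k in slot) {
      spec <- rule@triggers[[k]]
      if (usable(spec@channel)) { slot_ok <- TRUE; break }
      if (!is.na(spec@fallback) && usable(spec@fallback)) {
        slot_ok <- TRUE; break
      }
      slot_missing <- c(slot_missing, spec@channel)
    }
    if (!slot_ok) {
      eligible <- FALSE
      missing <- c(missing, slot_missing)
    }
  }
  list(eligible = eligible, missing = unique(missing))
}

.emptyAlarms <- function() {
  out <- data.frame(patient_id = character(0), scenario = character(0),
                    t_fire = numeric(0))
  for (k in 1:4) {
    out[[sprintf("trigger_%d_on", k)]] <- numeric(0)
    out[[sprintf("trigger_%d_off", k)]] <- numeric(0)
  }
  out
}

#' Evaluate a scenario rule over a patient record
#'
#' Implements the conjunction ("ALL-of") semantics of cross-sensor alarms:
#' the rule fires at the earliest instant `t` at which every trigger slot
#' has an active interval overlapping `[t - coOccurrence, t]`. After firing,
#' the rule is silent for `refractory` seconds (no two alarms from the same
#' rule are ever closer than the refractory period). Records that fail
#' [sensorsPresent()] yield no alarms and are flagged ineligible.
#'
#' @param record a [PatientRecord-class].
#' @param rule a [ScenarioRule-class].
#' @param coOccurrence,refractory seconds; default to the rule's values.
#' @param rate,gapTolerance,smoothing trigger-evaluation grid parameters.
#' @param plausibility optional named list `channel -> c(low, high)` of
#'   plausibility limits applied via [plausibilityFilter()] before trigger
#'   evaluation. Ignored (with a message) when `compatibilityMode = TRUE`,
#'   where a parameter may be consulted at most once per rule.
#' @param compatibilityMode logical; reproduce the constraint of the study
#'   software that forbade re-using a sensor's parameter within a
#'   definition, which precludes plausibility screening.
#' @return data.frame of alarms: `patient_id`, `scenario`, `t_fire`, and
#'   `trigger_k_on`/`trigger_k_off` for the contributing active interval of
#'   each trigger (NA for unengaged members of an either/or slot).
#'   Attributes `eligible` (logical) and `missingChannels`.
#' @export
evalScenario <- function(record, rule, coOccurrence = rule@coOccurrence,
                         refractory = rule@refractory, rate = 1,
                         gapTolerance = 10, smoothing = 10,
                         plausibility = NULL, compatibilityMode = FALSE) {
  stopifnot(is(record, "PatientRecord"), is(rule, "ScenarioRule"))
  if (length(rule@triggers) == 0L)
    stop("rule has zero triggers", call. = FALSE)
  if (compatibilityMode && !is.null(plausibility)) {
    plausibility <- NULL
  }
  pres <- sensorsPresent(record, rule, rate = rate,
                         gapTolerance = gapTolerance)
  out <- .emptyAlarms()
  if (!pres$eligible) {
    attr(out, "eligible") <- FALSE
    attr(out, "missingChannels") <- pres$missing
    return(out)
  }
  times <- seq(0, record@duration, by = 1 / rate)
  n <- length(times)
  ntrig <- length(rule@triggers)
  intervals <- vector("list", ntrig)
  active <- vector("list", ntrig)
  for (k in seq_len(ntrig)) {
    spec <- rule@triggers[[k]]
    trc <- .resolveTrace(record, spec)
    if (is.null(trc)) {                       # absent either/or member
      intervals[[k]] <- .emptyIntervals()
      active[[k]] <- rep(FALSE, n)
      next
    }
    src <- if (trc@channel == spec@channel) spec@channel else trc@channel
    if (!is.null(plausibility) && src %in% names(plausibility)) {
      lim <- plausibility[[src]]
      trc <- plausibilityFilter(trc, lim[1], lim[2])$trace
    }
    iv <- evalTrigger(trc, spec, rate = rate, gapTolerance = gapTolerance,
                      smoothing = smoothing)
    intervals[[k]] <- iv
    act <- rep(FALSE, n)
    if (nrow(iv)) {
      for (r in seq_len(nrow(iv))) {
        i0 <- max(1L, ceiling(iv$t_on[r] * rate) + 1L)
        i1 <- min(n, floor((iv$t_off[r] + coOccurrence) * rate) + 1L)
        if (i0 <= i1) act[i0:i1] <- TRUE
      }
    }
    active[[k]] <- act
  }
  all_active <- rep(TRUE, n)
  for (slot in .ruleSlots(rule)) {
    slot_active <- Reduce(`|`, active[slot])
    all_active <- all_active & slot_active
  }
  cand <- times[all_active]
  fires <- numeric(0)
  t_next <- -Inf
  for (tc in cand) {
    if (tc >= t_next) {
      fires <- c(fires, tc)
      t_next <- tc + refractory
    }
  }
  if (length(fires)) {
    out <- data.frame(patient_id = rep(record@patientId, length(fires)),
                      scenario = rep(rule@name, length(fires)),
                      t_fire = fires, stringsAsFactors = FALSE)
    for (k in 1:4) {
      on_col <- rep(NA_real_, length(fires))
      off_col <- rep(NA_real_, length(fires))
      if (k <= ntrig && nrow(intervals[[k]])) {
        iv <- intervals[[k]]
        for (j in seq_along(fires)) {
          hit <- which(iv$t_on <= fires[j] &
                         iv$t_off + coOccurrence >= fires[j])
          if (length(hit)) {
            hit <- hit[1]
            on_col[j] <- iv$t_on[hit]
            off_col[j] <- iv$t_off[hit]
          }
        }
      }
      out[[sprintf("trigger_%d_on", k)]] <- on_col
      out[[sprintf("trigger_%d_off", k)]] <- off_col
    }
  }
  attr(out, "eligible") <- TRUE
  attr(out, "missingChannels") <- character(0)
  out
}

#' Run a rule set over a cohort of records
#'
#' @param records list of [PatientRecord-class].
#' @param rules list of [ScenarioRule-class] (default: the five built-ins).
#' @param ... engine options passed to [evalScenario()]
#'   (`coOccurrence`, `refractory`, `plausibility`, `compatibilityMode`,
#'   grid parameters). `coOccurrence`/`refractory` default per rule.
#' @return List with `alarms` (data.frame sorted by patient, time, scenario)
#'   and `eligibility` (data.frame: `patient_id`, `scenario`, `eligible`,
#'   `missing_channels`).
#' @export
detectAlarms <- function(records, rules = builtinScenarios(), ...) {
  if (is(records, "PatientRecord")) records <- list(records)
  alarm_list <- list()
  elig_list <- list()
  for (rec in records) {
    for (rule in rules) {
      a <- evalScenario(rec, rule, ...)
      elig_list[[length(elig_list) + 1L]] <- data.frame(
        patient_id = rec@patientId, scenario = rule@name,
        eligible = attr(a, "eligible"),
        missing_channels = paste(attr(a, "missingChannels"),
                                 collapse = ";"),
        stringsAsFactors = FALSE)
      if (nrow(a)) alarm_list[[length(alarm_list) + 1L]] <- a
    }
  }
  alarms <- if (length(alarm_list)) do.call(rbind, alarm_list)
            else .emptyAlarms()
  alarms <- alarms[order(alarms$patient_id, alarms$t_fire,
                         alarms$scenario), , drop = FALSE]
  rownames(alarms) <- NULL
  list(alarms = alarms, eligibility = do.call(rbind, elig_list))
}

#' Write an alarm log CSV
#'
#' Columns `patient_id,scenario,t_fire,trigger_1_on,...` in deterministic
#' order (patient, time, scenario name).
#'
#' @param alarms alarm data.frame from [detectAlarms()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeAlarmLog <- function(alarms, path) {
  alarms <- alarms[order(alarms$patient_id, alarms$t_fire,
                         alarms$scenario), , drop = FALSE]
  utils::write.csv(alarms, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
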