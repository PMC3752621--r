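# Seeded generator of synthetic ICU records with labelled clinical episodes
# and sensor artifacts. Episode trajectories are deterministic ramp/hold/
# recovery shapes whose plateau values are derived arithmetically from the
# rule limits and a severity margin, so ground truth about detectability is
# analytic rather than empirical.

.episodeKinds <- function() c("svt_bp", "vtach_bp", "lv_shock", "tamponade",
                              "hypovolemia")

.artifactKinds <- function() c("artifact_cvp_spike", "artifact_damped_art",
                               "artifact_level_error", "artifact_motion",
                               "sensor_off", "confounder")

#' Map between scenario names and truth-event kinds
#'
#' @param kind truth-event kind (e.g. `"svt_bp"`).
#' @param scenario scenario name (e.g. `"SVT+BP"`).
#' @return The corresponding scenario name / kind, or `NA`.
#' @export
scenarioForKind <- function(kind) {
  map <- c(svt_bp = "SVT+BP", vtach_bp = "Vtach+BP", lv_shock = "LV shock",
           tamponade = "Tamponade", hypovolemia = "Hypovolemia")
  unname(map[kind])
}

#' @rdname scenarioForKind
#' @export
kindForScenario <- function(scenario) {
  map <- c("SVT+BP" = "svt_bp", "Vtach+BP" = "vtach_bp",
           "LV shock" = "lv_shock", "Tamponade" = "tamponade",
           "Hypovolemia" = "hypovolemia")
  unname(map[scenario])
}

#' Default per-channel noise model
#'
#' Stationary lag-1 autoregressive wander around stable baselines, with
#' marginal means/SDs typical of a haemodynamically stable postoperative
#' cardiac-surgery patient and autocorrelation 0.95 at 1 Hz (minute-scale
#' physiological wander). The pulse-oximeter `Pulse` rate is generated as
#' the ECG `HR` plus small independent sensor noise, so the two sensors
#' agree except during motion artifacts.
#'
#' @return data.frame with columns `channel`, `mean`, `sd`, `phi`.
#' @export
defaultNoiseModel <- function() {
  data.frame(
    channel = c("HR", "Pulse", "ARTsys", "ARTmean", "CVPmean", "PAPdia",
                "Perf", "NIBPm", "PVC", "VtachFlag"),
    mean = c(80, 80, 120, 85, 8, 12, 2.0, 85, 1, 0),
    sd   = c(4, 0.5, 6, 5, 2, 2, 0.3, 5, 1, 0),
    phi  = c(0.95, 0.8, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.9, 0),
    stringsAsFactors = FALSE
  )
}

#' Construct a cohort specification
#'
#' @param nPatients number of patients (the study unit had 10 beds).
#' @param duration seconds per record (default one patient-day, 86400 s).
#' @param plan data.frame with columns `kind`, `count`, `margin`; see
#'   [CohortSpec-class]. Default: empty plan (baseline noise only).
#' @param noise per-channel noise model (default [defaultNoiseModel()]).
#' @param seed integer master seed; per-patient seeds are derived from it by
#'   a counter-based scheme, so patient k's record does not change when the
#'   cohort size changes.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nPatients = 10, duration = 86400,
                       plan = data.frame(kind = character(0),
                                         count = integer(0),
                                         margin = numeric(0)),
                       noise = defaultNoiseModel(), seed = 1L) {
  new("CohortSpec", nPatients = as.numeric(nPatients),
      duration = as.numeric(duration), plan = plan, noise = noise,
      seed = as.numeric(seed))
}

# Stationary AR(1) series: marginal mean/sd as given, lag-1 autocorrelation
# phi; innovations scaled so the stationary variance equals sd^2.
.ar1 <- function(n, mean, sd, phi) {
  if (sd == 0) return(rep(mean, n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  x <- stats::filter(e, phi, method = "recursive",
                     init = stats::rnorm(1, 0, sd))
  mean + as.numeric(x)
}

.clipChannel <- function(channel, v) {
  rng <- .channelRange(channel)
  pmin(pmax(v, rng[1]), rng[2])
}

# ---- episode geometry and targets ------------------------------------------

# ramp/hold/recovery lengths (s) for a clinical episode kind. The ramp must
# complete well inside the shortest relative-trigger window so the change is
# visible to the trigger; the hold must outlast the longest persistence
# requirement plus the co-occurrence window.
.episodeGeometry <- function(kind) {
  rule <- .builtinByKind(kind)
  windows <- vapply(rule@triggers, function(tr)
    if (tr@kind == "relative_change") tr@window else Inf, 0)
  durations <- vapply(rule@triggers, function(tr)
    if (tr@kind == "relative_change") 0 else tr@duration, 0)
  ramp <- min(30, floor(min(windows) / 2))
  hold <- max(durations) + 60
  list(rule = rule, ramp = ramp, hold = hold, recovery = 120,
       total = ramp + hold + 120)
}

.builtinByKind <- function(kind) {
  sc <- scenarioForKind(kind)
  rules <- builtinScenarios()
  rules[[which(vapply(rules, ruleName, "") == sc)]]
}

# Per-channel plateau targets for an episode. margin > 0 exceeds every
# trigger limit by that fraction (multiplicative on thresholds and percent
# changes, additive-scaled on native deltas); margin < 0 undershoots every
# limit the same way. HR and Pulse report the same physiology, so when both
# appear in a rule they share the more constraining target.
.episodeTargets <- function(rule, margin, baselines) {
  up <- list(); down <- list()
  add <- function(store, ch, val) {
    store[[ch]] <- c(store[[ch]], val); store
  }
  for (tr in rule@triggers) {
    ch <- tr@channel
    base <- baselines[[ch]]
    if (tr@kind == "flag_present") next
    if (tr@kind == "absolute_sustained") {
      if (tr@direction == "above") up <- add(up, ch, tr@threshold * (1 + margin))
      else down <- add(down, ch, tr@threshold * (1 - margin))
    } else {
      frac <- tr@threshold / 100
      if (tr@unit == "native") {
        if (tr@direction == "rise")
          up <- add(up, ch, base + tr@threshold * (1 + margin))
        else down <- add(down, ch, base - tr@threshold * (1 + margin))
      } else if (tr@direction == "rise") {
        up <- add(up, ch, base * (1 + frac * (1 + margin)))
      } else {
        down <- add(down, ch, base * (1 - frac * (1 + margin)))
      }
    }
  }
  pick <- function(vals, dir_up) {
    if (margin > 0) { if (dir_up) max(vals) else min(vals) }
    else { if (dir_up) min(vals) else max(vals) }
  }
  targets <- list()
  for (ch in names(up)) targets[[ch]] <- pick(up[[ch]], TRUE)
  for (ch in names(down)) targets[[ch]] <- pick(down[[ch]], FALSE)
  hp <- intersect(c("HR", "Pulse"), names(targets))
  if (length(hp) == 2L) {
    shared <- if (margin > 0) max(unlist(targets[hp]))
              else min(unlist(targets[hp]))
    targets[["HR"]] <- shared
    targets[["Pulse"]] <- shared
  }
  targets
}

# Replace trace values with a deterministic ramp/hold/recovery trajectory.
# Assumes the trace sits on the 1 Hz grid t = 0..duration-1 (as generated
# records do).
.applyTrajectory <- function(record, channel, t0, ramp, hold, recovery,
                             target, base = NULL) {
  tr <- getTrace(record, channel)
  if (is.null(tr)) return(record)
  v <- tr@value
  idx0 <- which(tr@t >= t0)[1]
  if (is.na(idx0)) return(record)
  if (is.null(base)) {
    pre <- v[tr@t >= t0 - 10 & tr@t < t0]
    base <- if (all(is.na(pre))) target else stats::median(pre, na.rm = TRUE)
  }
  n <- length(v)
  seqIdx <- function(a, b) if (a > min(b, n)) integer(0) else a:min(b, n)
  ramp_idx <- seqIdx(idx0, idx0 + ramp - 1L)
  hold_idx <- seqIdx(idx0 + ramp, idx0 + ramp + hold - 1L)
  rec_idx <- seqIdx(idx0 + ramp + hold, idx0 + ramp + hold + recovery - 1L)
  if (ramp > 0 && length(ramp_idx))
    v[ramp_idx] <- base + (target - base) *
      seq_along(ramp_idx) / max(1L, ramp)
  if (length(hold_idx))
    v[hold_idx] <- target
  if (recovery > 0 && length(rec_idx))
    v[rec_idx] <- target + (base - target) *
      seq_along(rec_idx) / length(rec_idx)
  v <- .clipChannel(channel, v)
  record@traces[[channel]] <- new("VitalTrace", channel = channel,
                                  t = tr@t, value = v, rate = tr@rate)
  record
}

# Local pre-episode baseline per channel: median of the 10 s preceding
# onset, matching the smoothing reference the relative triggers use, so a
# percent-change plateau derived from it is judged against (almost) the
# same quantity at evaluation time.
.localBaselines <- function(record, chans, t0) {
  out <- list()
  for (ch in chans) {
    tr <- getTrace(record, ch)
    if (is.null(tr)) { out[[ch]] <- NA_real_; next }
    pre <- tr@value[tr@t >= t0 - 10 & tr@t < t0]
    out[[ch]] <- stats::median(pre, na.rm = TRUE)
  }
  out
}

#' Inject a clinical episode into a record
#'
#' Ramps the channels referenced by the episode's scenario rule from their
#' local baseline to plateau values that exceed (`margin > 0`) or undershoot
#' (`margin < 0`) every trigger limit of the rule by `|margin|` (see
#' [CohortSpec-class]), holds the plateau for the longest trigger
#' persistence plus 60 s, then recovers linearly over 120 s. The plateau is
#' deterministic, so whether each trigger fires is decidable by arithmetic.
#'
#' @param record a [PatientRecord-class] on the 1 Hz grid.
#' @param kind one of `svt_bp`, `vtach_bp`, `lv_shock`, `tamponade`,
#'   `hypovolemia`.
#' @param t0 episode onset in seconds.
#' @param margin severity margin (fraction; e.g. `0.1` = every limit
#'   exceeded by 10%).
#' @return List with the modified `record` and a one-row `truth`
#'   data.frame (`kind`, `t_start`, `t_end`, `intended_detectable`).
#' @export
injectEpisode <- function(record, kind, t0, margin = 0.1) {
  if (!(kind %in% .episodeKinds()))
    stop("unknown episode kind: ", kind, call. = FALSE)
  geom <- .episodeGeometry(kind)
  if (t0 + geom$total > record@duration)
    stop("episode does not fit in record (scheduling error)", call. = FALSE)
  rule <- geom$rule
  chans <- unique(vapply(rule@triggers, function(tr) tr@channel, ""))
  base <- .localBaselines(record, chans, t0)
  targets <- .episodeTargets(rule, margin, base)
  for (ch in names(targets))
    record <- .applyTrajectory(record, ch, t0, geom$ramp, geom$hold,
                               geom$recovery, targets[[ch]],
                               base = base[[ch]])
  if ("VtachFlag" %in% chans) {
    flag_len <- if (margin > 0) geom$hold else max(0, floor(5 * (1 + margin)))
    tr <- getTrace(record, "VtachFlag")
    if (!is.null(tr) && flag_len > 0) {
      v <- tr@value
      on <- which(tr@t >= t0 + geom$ramp & tr@t < t0 + geom$ramp + flag_len)
      v[on] <- 1
      record@traces[["VtachFlag"]] <- new("VitalTrace",
        channel = "VtachFlag", t = tr@t, value = v, rate = tr@rate)
    }
  }
  truth <- data.frame(kind = kind, t_start = t0, t_end = t0 + geom$total,
                      intended_detectable = margin > 0,
                      stringsAsFactors = FALSE)
  list(record = record, truth = truth)
}

#' Inject a sensor artifact into a record
#'
#' Artifact kinds reproduce the failure modes seen around arterial and
#' central venous catheters and ECG leads:
#' * `artifact_cvp_spike` — an infusion running into the CVP line drives the
#'   reading to `params$value` (default 200 mmHg) for `params$duration`
#'   (default 120 s). With `params$provoke = TRUE` the injection models the
#'   bedside reality that such artifacts cluster with other transducer
#'   disturbances (flushing, repositioning, leveling): ARTsys damping,
#'   a PAPdia offset and a perfusion-index droop are co-injected at
#'   `params$margin` (default 0.1) beyond the obstructive-shock limits, so
#'   the tamponade conjunction fires — unless the CVP plausibility screen
#'   removes the extreme reading, in which case the conjunction fails.
#' * `artifact_damped_art` — a damped arterial waveform: ARTsys collapses to
#'   `params$value` (default 70 mmHg, satisfying the hypotension criterion)
#'   for `params$duration` (default 400 s) while cuff pressure stays normal.
#' * `artifact_level_error` — transducer leveling error: constant
#'   `params$offset` (default +20 mmHg) on `params$channel`
#'   (default CVPmean) for `params$duration` (default 600 s).
#' * `artifact_motion` — patient motion: ECG HR spikes and Vtach-flag
#'   bursts for `params$duration` (default 60 s) while the pulse-oximeter
#'   Pulse stays at baseline.
#' * `sensor_off` — `params$channels` (default the ECG-derived HR, PVC,
#'   VtachFlag) go missing for `params$duration` (default 300 s).
#'
#' @param record a [PatientRecord-class] on the 1 Hz grid.
#' @param kind artifact kind (see above).
#' @param t0 artifact onset in seconds.
#' @param params list of kind-specific parameters.
#' @return List with the modified `record` and a one-row `truth`
#'   data.frame; `intended_detectable` is `TRUE` only for the
#'   alarm-provoking compound CVP-spike variant.
#' @export
injectArtifact <- function(record, kind, t0, params = list()) {
  p <- params
  truth_detect <- FALSE
  if (kind == "artifact_cvp_spike") {
    value <- p$value %||% 200
    provoke <- isTRUE(p$provoke)
    margin <- p$margin %||% 0.1
    if (provoke) {
      duration <- p$duration %||% 240
      base <- .localBaselines(record, c("ARTsys", "PAPdia", "Perf"), t0)
      record <- .applyTrajectory(record, "CVPmean", t0, 30, duration, 120,
                                 value)
      record <- .applyTrajectory(record, "ARTsys", t0, 30, duration, 120,
                                 78 * (1 - margin), base = base$ARTsys)
      record <- .applyTrajectory(record, "PAPdia", t0, 30, duration, 120,
                                 16 * (1 + margin), base = base$PAPdia)
      record <- .applyTrajectory(record, "Perf", t0, 30, duration, 120,
                                 base$Perf * (1 - 0.20 * (1 + margin)),
                                 base = base$Perf)
      total <- 30 + duration + 120
      truth_detect <- TRUE
    } else {
      duration <- p$duration %||% 120
      record <- .applyTrajectory(record, "CVPmean", t0, 5, duration, 5,
                                 value)
      total <- 5 + duration + 5
    }
  } else if (kind == "artifact_damped_art") {
    value <- p$value %||% 70
    duration <- p$duration %||% 400
    record <- .applyTrajectory(record, "ARTsys", t0, 20, duration, 60,
                               value)
    total <- 20 + duration + 60
  } else if (kind == "artifact_level_error") {
    channel <- p$channel %||% "CVPmean"
    offset <- p$offset %||% 20
    duration <- p$duration %||% 600
    tr <- getTrace(record, channel)
    if (!is.null(tr)) {
      v <- tr@value
      idx <- which(tr@t >= t0 & tr@t < t0 + duration)
      v[idx] <- .clipChannel(channel, v[idx] + offset)
      record@traces[[channel]] <- new("VitalTrace", channel = channel,
                                      t = tr@t, value = v, rate = tr@rate)
    }
    total <- duration
  } else if (kind == "artifact_motion") {
    duration <- p$duration %||% 60
    tr <- getTrace(record, "HR")
    if (!is.null(tr)) {
      v <- tr@value
      idx <- which(tr@t >= t0 & tr@t < t0 + duration)
      burst <- (seq_along(idx) - 1L) %/% 5L %% 2L == 0L
      v[idx][burst] <- .clipChannel("HR", v[idx][burst] + 80)
      record@traces[["HR"]] <- new("VitalTrace", channel = "HR", t = tr@t,
                                   value = v, rate = tr@rate)
    }
    fl <- getTrace(record, "VtachFlag")
    if (!is.null(fl)) {
      v <- fl@value
      v[fl@t >= t0 & fl@t < t0 + duration] <- 1
      record@traces[["VtachFlag"]] <- new("VitalTrace",
        channel = "VtachFlag", t = fl@t, value = v, rate = fl@rate)
    }
    total <- duration
  } else if (kind == "sensor_off") {
    channels <- p$channels %||% c("HR", "PVC", "VtachFlag")
    duration <- p$duration %||% 300
    for (ch in channels) {
      tr <- getTrace(record, ch)
      if (is.null(tr)) next
      v <- tr@value
      v[tr@t >= t0 & tr@t < t0 + duration] <- NA_real_
      record@traces[[ch]] <- new("VitalTrace", channel = ch, t = tr@t,
                                 value = v, rate = tr@rate)
    }
    total <- duration
  } else {
    stop("unknown artifact kind: ", kind, call. = FALSE)
  }
  if (t0 + total > record@duration)
    stop("artifact does not fit in record (scheduling error)",
         call. = FALSE)
  truth <- data.frame(kind = kind, t_start = t0, t_end = t0 + total,
                      intended_detectable = truth_detect,
                      stringsAsFactors = FALSE)
  list(record = record, truth = truth)
}

.planItemLength <- function(kind, margin) {
  if (kind %in% .episodeKinds()) return(.episodeGeometry(kind)$total)
  switch(kind,
    artifact_cvp_spike = if (margin > 0) 390 else 130,
    artifact_damped_art = 480,
    artifact_level_error = 600,
    artifact_motion = 60,
    sensor_off = 300,
    confounder = 300)
}

#' Simulate one patient record with planned episodes and artifacts
#'
#' Generates baseline AR(1) wander for every channel of the noise model,
#' then schedules and injects the planned items sequentially with at least
#' 600 s between them (so refractory periods and relative-trigger lookbacks
#' of consecutive episodes cannot interact). Deterministic given `seed`.
#'
#' @param spec a [CohortSpec-class] (only `duration` and `noise` are used
#'   here; the plan comes from `planItems`).
#' @param seed integer seed for this patient.
#' @param patientId patient identifier.
#' @param planItems data.frame with columns `kind`, `margin`, one row per
#'   item to embed (default: the expansion of `spec@plan`).
#' @return List with `record` ([PatientRecord-class]) and `truth`
#'   (data.frame with `patient_id`, `kind`, `t_start`, `t_end`,
#'   `intended_detectable`).
#' @export
simulatePatient <- function(spec, seed, patientId = "p1",
                            planItems = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  if (is.null(planItems)) planItems <- .expandPlan(spec@plan)
  set.seed(as.integer(seed))
  n <- as.integer(spec@duration)
  tgrid <- seq(0, n - 1)
  noise <- spec@noise
  values <- list()
  hr_row <- noise[noise$channel == "HR", ]
  hr <- if (nrow(hr_row)) .ar1(n, hr_row$mean, hr_row$sd, hr_row$phi)
        else NULL
  for (i in seq_len(nrow(noise))) {
    ch <- noise$channel[i]
    if (ch == "Pulse" && !is.null(hr)) {
      v <- hr + .ar1(n, 0, noise$sd[i], noise$phi[i])
    } else if (ch == "HR" && !is.null(hr)) {
      v <- hr
    } else if (ch == "PVC") {
      v <- round(pmax(0, .ar1(n, noise$mean[i], noise$sd[i], noise$phi[i])))
    } else if (ch == "VtachFlag") {
      v <- rep(0, n)
    } else {
      v <- .ar1(n, noise$mean[i], noise$sd[i], noise$phi[i])
    }
    values[[ch]] <- .clipChannel(ch, v)
  }
  record <- patientRecord(patientId, spec@duration,
    lapply(names(values), function(ch) makeTrace(ch, tgrid, values[[ch]])))
  truths <- list()
  if (nrow(planItems)) {
    ord <- sample.int(nrow(planItems))
    planItems <- planItems[ord, , drop = FALSE]
    t_cursor <- 600
    for (r in seq_len(nrow(planItems))) {
      kind <- planItems$kind[r]
      margin <- planItems$margin[r]
      t0 <- floor(t_cursor + stats::runif(1, 0, 120))
      len <- .planItemLength(kind, margin)
      if (t0 + len + 60 > spec@duration)
        stop("episode plan does not fit in record duration ",
             "(scheduling error)", call. = FALSE)
      if (kind %in% .episodeKinds()) {
        res <- injectEpisode(record, kind, t0, margin)
      } else if (kind == "confounder") {
        res <- list(record = record,
                    truth = data.frame(kind = "confounder", t_start = t0,
                                       t_end = t0 + len,
                                       intended_detectable = FALSE,
                                       stringsAsFactors = FALSE))
      } else {
        res <- injectArtifact(record, kind, t0,
                              params = list(provoke = margin > 0,
                                            margin = abs(margin)))
      }
      record <- res$record
      truths[[length(truths) + 1L]] <- res$truth
      t_cursor <- t0 + len + 600
    }
  }
  truth <- if (length(truths)) do.call(rbind, truths)
           else data.frame(kind = character(0), t_start = numeric(0),
                           t_end = numeric(0),
                           intended_detectable = logical(0))
  if (nrow(truth))
    truth <- cbind(patient_id = patientId, truth, stringsAsFactors = FALSE)
  else truth <- cbind(data.frame(patient_id = character(0)), truth)
  list(record = record, truth = truth)
}

.expandPlan <- function(plan) {
  if (!nrow(plan))
    return(data.frame(kind = character(0), margin = numeric(0)))
  items <- plan[rep(seq_len(nrow(plan)), plan$count), c("kind", "margin"),
                drop = FALSE]
  rownames(items) <- NULL
  items
}

#' Simulate a monitored cohort
#'
#' Expands the cohort plan, deals items round-robin across patients, and
#' simulates each patient with a seed derived deterministically from the
#' master seed.
#'
#' @param spec a [CohortSpec-class].
#' @return List with `records` (list of [PatientRecord-class]) and `truth`
#'   (combined truth log data.frame).
#' @examples
#' spec <- cohortSpec(nPatients = 1, duration = 3600,
#'                    plan = data.frame(kind = "lv_shock", count = 1,
#'                                      margin = 0.1), seed = 7)
#' sim <- simulateCohort(spec)
#' sim$truth
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  np <- as.integer(spec@nPatients)
  items <- .expandPlan(spec@plan)
  assign_to <- if (nrow(items)) rep_len(seq_len(np), nrow(items))
               else integer(0)
  records <- vector("list", np)
  truths <- list()
  for (i in seq_len(np)) {
    pid <- sprintf("p%02d", i)
    mine <- items[assign_to == i, , drop = FALSE]
    res <- simulatePatient(spec, seed = .deriveSeed(spec@seed, i),
                           patientId = pid, planItems = mine)
    records[[i]] <- res$record
    if (nrow(res$truth)) truths[[length(truths) + 1L]] <- res$truth
  }
  truth <- if (length(truths)) do.call(rbind, truths)
           else data.frame(patient_id = character(0), kind = character(0),
                           t_start = numeric(0), t_end = numeric(0),
                           intended_detectable = logical(0))
  rownames(truth) <- NULL
  list(records = records, truth = truth)
}

#' Read and write truth logs
#'
#' Truth log CSV: `patient_id,kind,t_start,t_end,intended_detectable`.
#'
#' @param truth truth data.frame.
#' @param path CSV path.
#' @return `writeTruthLog` returns `path` invisibly; `readTruthLog` returns
#'   the truth data.frame.
#' @export
writeTruthLog <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTruthLog
#' @export
readTruthLog <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
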