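#' @import methods
NULL

#' VitalTrace: one channel's timestamped value series
#'
#' A single monitor numeric over time for one patient. Timestamps are seconds
#' from record start and must be strictly increasing; values are in the
#' channel's native units with `NA` marking missing data. Non-missing values
#' must lie inside the channel's carrier range (see [channelInfo()]); the
#' carrier range is wide enough to admit artifactual readings such as a
#' 200 mmHg CVP, which are screened only by the optional plausibility filter.
#'
#' @slot channel single channel identifier (see [channelInfo()]).
#' @slot t numeric vector of timestamps (seconds from record start).
#' @slot value numeric vector, same length as `t`; `NA` = missing.
#' @slot rate nominal sampling rate in samples/second.
#' @seealso [makeTrace()], [resampleUniform()], [baselineValue()]
#' @export
setClass("VitalTrace",
  representation(channel = "character", t = "numeric", value = "numeric",
                 rate = "numeric"),
  prototype(rate = 1)
)

setValidity("VitalTrace", function(object) {
  msgs <- character(0)
  if (length(object@channel) != 1L || !(object@channel %in% .channelIds()))
    msgs <- c(msgs, "channel must be one of the registered channel ids")
  if (length(object@t) != length(object@value))
    msgs <- c(msgs, "t and value must have the same length")
  if (length(object@t) == 0L)
    msgs <- c(msgs, "trace must contain at least one sample")
  if (anyNA(object@t))
    msgs <- c(msgs, "timestamps must not be missing")
  if (length(object@t) > 1L && any(diff(object@t) <= 0))
    msgs <- c(msgs, "timestamps must be strictly increasing")
  if (length(object@rate) != 1L || is.na(object@rate) || object@rate <= 0)
    msgs <- c(msgs, "rate must be a positive scalar")
  if (length(object@channel) == 1L && object@channel %in% .channelIds()) {
    rng <- .channelRange(object@channel)
    v <- object@value[!is.na(object@value)]
    if (length(v) && (any(v < rng[1]) || any(v > rng[2])))
      msgs <- c(msgs, sprintf("values outside carrier range [%g, %g] for %s",
                              rng[1], rng[2], object@channel))
    if (object@channel == "VtachFlag" && length(v) && !all(v %in% c(0, 1)))
      msgs <- c(msgs, "VtachFlag values must be 0 or 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' PatientRecord: a multichannel vital-sign record for one patient
#'
#' Holds one [VitalTrace-class] per available channel. A channel may be
#' absent (e.g. no arterial line); scenario eligibility checks
#' ([sensorsPresent()]) react to absence, mirroring the study exclusion rule
#' that events were not analyzed when the requisite sensors were missing.
#'
#' @slot patientId patient identifier.
#' @slot duration record length in seconds; all trace timestamps lie in
#'   `[0, duration]`.
#' @slot traces named list of [VitalTrace-class] objects, names = channels.
#' @export
setClass("PatientRecord",
  representation(patientId = "character", duration = "numeric",
                 traces = "list")
)

setValidity("PatientRecord", function(object) {
  msgs <- character(0)
  if (length(object@patientId) != 1L || !nzchar(object@patientId))
    msgs <- c(msgs, "patientId must be a non-empty string")
  if (length(object@duration) != 1L || is.na(object@duration) ||
      object@duration <= 0)
    msgs <- c(msgs, "duration must be a positive scalar")
  for (nm in names(object@traces)) {
    tr <- object@traces[[nm]]
    if (!is(tr, "VitalTrace")) {
      msgs <- c(msgs, "traces must all be VitalTrace objects")
      next
    }
    if (!identical(tr@channel, nm))
      msgs <- c(msgs, sprintf("trace stored under '%s' has channel '%s'",
                              nm, tr@channel))
    if (min(tr@t) < 0 || max(tr@t) > object@duration)
      msgs <- c(msgs, sprintf("trace %s has timestamps outside [0, duration]",
                              nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' TriggerSpec: one single-parameter trigger of an alarm scenario
#'
#' Three kinds are supported, matching how bedside event-surveillance rules
#' are written:
#' * `absolute_sustained` — the value is strictly beyond `threshold`
#'   (direction `above`/`below`) continuously for `duration` seconds;
#' * `relative_change` — the smoothed value differs from an earlier baseline
#'   by at least `threshold` (percent of baseline when `unit = "percent"`,
#'   channel units when `unit = "native"`, direction `rise`/`fall`) for some
#'   lag within `window` seconds;
#' * `flag_present` — a 0/1 annotation channel is 1 continuously for
#'   `duration` seconds.
#'
#' `fallback` names an interchangeable source for the same physiology, as in
#' the "HR (Pulse)" notation of monitor rule tables: the fallback channel is
#' used when the primary is absent from a record. `scope` (relative triggers
#' only) keeps a satisfied relative trigger active for `scope - window`
#' further seconds, supporting rules written as "within 120 sec / 10 min".
#'
#' @slot channel,fallback channel ids (`fallback` may be `NA`).
#' @slot kind one of `absolute_sustained`, `relative_change`, `flag_present`.
#' @slot direction `above`/`below` (absolute) or `rise`/`fall` (relative).
#' @slot threshold numeric threshold (units per `unit`).
#' @slot unit `"native"` or `"percent"`.
#' @slot duration persistence requirement in seconds (absolute/flag kinds).
#' @slot window lookback in seconds (relative kind).
#' @slot scope activity scope in seconds (relative kind; `NA` = `window`).
#' @seealso [triggerSpec()], [evalTrigger()]
#' @export
setClass("TriggerSpec",
  representation(channel = "character", fallback = "character",
                 kind = "character", direction = "character",
                 threshold = "numeric", unit = "character",
                 duration = "numeric", window = "numeric", scope = "numeric")
)

setValidity("TriggerSpec", function(object) {
  msgs <- character(0)
  if (!(object@channel %in% .channelIds()))
    msgs <- c(msgs, "unknown channel")
  if (!is.na(object@fallback) && !(object@fallback %in% .channelIds()))
    msgs <- c(msgs, "unknown fallback channel")
  if (!(object@kind %in% c("absolute_sustained", "relative_change",
                           "flag_present")))
    msgs <- c(msgs, "unknown trigger kind")
  ok_dir <- switch(object@kind,
    absolute_sustained = c("above", "below"),
    relative_change = c("rise", "fall"),
    flag_present = "above",
    character(0))
  if (!(object@direction %in% ok_dir))
    msgs <- c(msgs, sprintf("direction '%s' invalid for kind '%s'",
                            object@direction, object@kind))
  if (!(object@unit %in% c("native", "percent")))
    msgs <- c(msgs, "unit must be 'native' or 'percent'")
  if (object@kind == "relative_change") {
    if (is.na(object@window) || object@window <= 0)
      msgs <- c(msgs, "relative_change requires window > 0")
    if (!is.na(object@duration))
      msgs <- c(msgs, "relative_change must not set duration")
    if (object@unit == "percent" &&
        (is.na(object@threshold) || object@threshold <= 0 ||
           object@threshold > 100))
      msgs <- c(msgs, "percent threshold must lie in (0, 100]")
    if (!is.na(object@scope) && object@scope < object@window)
      msgs <- c(msgs, "scope must be >= window")
  } else {
    if (is.na(object@duration) || object@duration <= 0)
      msgs <- c(msgs, paste0(object@kind, " requires duration > 0"))
    if (!is.na(object@window))
      msgs <- c(msgs, paste0(object@kind, " must not set window"))
    if (object@unit != "native")
      msgs <- c(msgs, "absolute/flag thresholds are in native units")
  }
  if (length(msgs)) msgs else TRUE
})

#' ScenarioRule: a named multi-parameter alarm definition
#'
#' A rule is 1-4 [TriggerSpec-class]s combined as a conjunction: the alarm
#' fires when every trigger slot has been active within a co-occurrence
#' window. Triggers whose channels appear together in an `eitherGroups` entry
#' share a slot satisfied by any of its members (e.g. the hypovolemia rule's
#' blood-pressure condition may come from the arterial line or the cuff).
#' After firing, the rule is silent for `refractory` seconds.
#'
#' @slot name,description scenario name and free-text description.
#' @slot triggers list of 1-4 [TriggerSpec-class].
#' @slot requiredChannels channels the rule depends on (superset of trigger
#'   channels after fallback resolution).
#' @slot eitherGroups list of character vectors; channels in one vector form
#'   a single either/or slot for both eligibility and conjunction.
#' @slot coOccurrence co-occurrence window in seconds.
#' @slot refractory refractory period in seconds.
#' @seealso [scenarioRule()], [builtinScenarios()], [evalScenario()]
#' @export
setClass("ScenarioRule",
  representation(name = "character", description = "character",
                 triggers = "list", requiredChannels = "character",
                 eitherGroups = "list", coOccurrence = "numeric",
                 refractory = "numeric")
)

setValidity("ScenarioRule", function(object) {
  msgs <- character(0)
  nt <- length(object@triggers)
  if (nt < 1L || nt > 4L)
    msgs <- c(msgs, "a rule holds between 1 and 4 triggers (maximum of four)")
  if (!all(vapply(object@triggers, function(x) is(x, "TriggerSpec"), TRUE)))
    msgs <- c(msgs, "triggers must be TriggerSpec objects")
  trig_ch <- unique(unlist(lapply(object@triggers, function(tr)
    c(tr@channel, if (!is.na(tr@fallback)) tr@fallback))))
  if (!all(trig_ch %in% object@requiredChannels))
    msgs <- c(msgs, "requiredChannels must cover all trigger channels")
  for (g in object@eitherGroups) {
    if (!all(g %in% vapply(object@triggers, function(tr) tr@channel, "")))
      msgs <- c(msgs, "eitherGroups must reference trigger channels")
  }
  if (length(object@coOccurrence) != 1L || object@coOccurrence < 0)
    msgs <- c(msgs, "coOccurrence must be a non-negative scalar")
  if (length(object@refractory) != 1L || object@refractory < 0)
    msgs <- c(msgs, "refractory must be a non-negative scalar")
  if (length(msgs)) msgs else TRUE
})

#' CohortSpec: plan for a synthetic monitored cohort
#'
#' Describes how many patients to simulate, for how long, which clinical
#' episodes and artifacts to embed (the plan), and the per-channel noise
#' model (stationary lag-1 autoregressive wander around a stable baseline).
#'
#' The `plan` data.frame has columns `kind` (episode or artifact kind),
#' `count`, and `margin` — the severity margin as a fraction beyond (+) or
#' short of (-) every trigger limit of the corresponding rule; episodes with
#' positive margin are designed to be detectable by construction, negative
#' margins are sub-threshold, and for artifacts a positive margin requests
#' the alarm-provoking compound variant.
#'
#' @slot nPatients number of patients.
#' @slot duration record length per patient in seconds.
#' @slot plan data.frame with columns `kind`, `count`, `margin`.
#' @slot noise data.frame with columns `channel`, `mean`, `sd`, `phi`
#'   (lag-1 autocorrelation).
#' @slot seed integer master seed.
#' @seealso [cohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec",
  representation(nPatients = "numeric", duration = "numeric",
                 plan = "data.frame", noise = "data.frame", seed = "numeric")
)

setValidity("CohortSpec", function(object) {
  msgs <- character(0)
  if (object@nPatients < 1) msgs <- c(msgs, "nPatients must be >= 1")
  if (object@duration < 600) msgs <- c(msgs, "duration must be >= 600 s")
  need <- c("kind", "count", "margin")
  if (!all(need %in% names(object@plan)))
    msgs <- c(msgs, "plan must have columns kind, count, margin")
  else {
    if (any(object@plan$count < 0)) msgs <- c(msgs, "plan counts must be >= 0")
    bad <- setdiff(object@plan$kind, c(.episodeKinds(), .artifactKinds()))
    if (length(bad))
      msgs <- c(msgs, paste0("unknown plan kinds: ", paste(bad, collapse = ",")))
  }
  if (!all(c("channel", "mean", "sd", "phi") %in% names(object@noise)))
    msgs <- c(msgs, "noise must have columns channel, mean, sd, phi")
  if (length(msgs)) msgs else TRUE
})
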