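#' Construct a scenario rule
#'
#' @param name scenario name.
#' @param triggers list of 1-4 [TriggerSpec-class] (monitor rule tables cap
#'   definitions at a maximum of four parameters).
#' @param description free-text description.
#' @param requiredChannels channels the rule depends on; defaults to the
#'   union of trigger channels and fallbacks.
#' @param eitherGroups list of character vectors; trigger channels listed in
#'   one vector form a single either/or slot for eligibility and for the
#'   conjunction (e.g. arterial line or cuff pressure).
#' @param coOccurrence co-occurrence window in seconds (default 60).
#' @param refractory refractory period in seconds (default 300).
#' @return A [ScenarioRule-class].
#' @export
scenarioRule <- function(name, triggers, description = "",
                         requiredChannels = NULL, eitherGroups = list(),
                         coOccurrence = 60, refractory = 300) {
  if (is(triggers, "TriggerSpec")) triggers <- list(triggers)
  if (length(triggers) > 4L)
    stop("a rule may hold a maximum of four triggers", call. = FALSE)
  if (is.null(requiredChannels))
    requiredChannels <- unique(unlist(lapply(triggers, function(tr)
      c(tr@channel, if (!is.na(tr@fallback)) tr@fallback))))
  new("ScenarioRule", name = name, description = description,
      triggers = triggers, requiredChannels = requiredChannels,
      eitherGroups = eitherGroups, coOccurrence = as.numeric(coOccurrence),
      refractory = as.numeric(refractory))
}

#' The five built-in haemodynamic alarm scenarios
#'
#' The cross-sensor alarm definitions programmed for a cardiothoracic ICU:
#' each combines up to four single-parameter triggers so that a firing alarm
#' reflects agreement across independent sensors.
#'
#' * **SVT+BP** — rapid supraventricular rate with hypotension (e.g.
#'   paroxysmal atrial fibrillation with rapid ventricular response):
#'   HR +40% within 59 s, ARTsys -15% within 59 s, Pulse >110 bpm for 20 s.
#' * **Vtach+BP** — ventricular tachycardia with hypotension: HR +30 bpm
#'   within 20 s, the monitor's Vtach rhythm annotation, ARTsys -30% within
#'   20 s, Pulse >110 bpm for 10 s.
#' * **LV shock** — cardiogenic shock: ARTsys <78 mmHg, CVPmean <16 mmHg,
#'   PAPdia >16 mmHg, Perf <1.2, each for 300 s.
#' * **Tamponade** — obstructive shock: ARTsys <78 mmHg, CVPmean >16 mmHg,
#'   PAPdia >16 mmHg for 180 s each, Perf -20% within 3 min.
#' * **Hypovolemia** — ARTmean <50 mmHg, CVPmean <5 mmHg, NIBPm <55 mmHg for
#'   300 s each, Perf -20% within 120 s (10-min scope); the two pressure
#'   sources (arterial line / cuff) form one either/or slot.
#'
#' The Vtach rhythm annotation is carried as the `VtachFlag` channel with a
#' 5-s persistence requirement; detection of the rhythm itself is the
#' monitor's job, outside this package. The `PVC` channel rides along in the
#' Vtach+BP required-channel set but carries no numeric limit of its own.
#'
#' @return List of five [ScenarioRule-class] objects.
#' @examples
#' vapply(builtinScenarios(), ruleName, "")
#' @export
builtinScenarios <- function() {
  list(
    scenarioRule("SVT+BP",
      description = paste("Supraventricular tachycardia with low blood",
                          "pressure (e.g. rapid atrial fibrillation)"),
      triggers = list(
        triggerSpec("HR", "relative_change", "rise", 40, unit = "percent",
                    window = 59, fallback = "Pulse"),
        triggerSpec("ARTsys", "relative_change", "fall", 15,
                    unit = "percent", window = 59),
        triggerSpec("Pulse", "absolute_sustained", "above", 110,
                    duration = 20, fallback = "HR"))),
    scenarioRule("Vtach+BP",
      description = "Ventricular tachycardia with low blood pressure",
      triggers = list(
        triggerSpec("HR", "relative_change", "rise", 30, unit = "native",
                    window = 20, fallback = "Pulse"),
        triggerSpec("VtachFlag", "flag_present", threshold = 1,
                    duration = 5),
        triggerSpec("ARTsys", "relative_change", "fall", 30,
                    unit = "percent", window = 20),
        triggerSpec("Pulse", "absolute_sustained", "above", 110,
                    duration = 10, fallback = "HR")),
      requiredChannels = c("HR", "Pulse", "VtachFlag", "PVC", "ARTsys")),
    scenarioRule("LV shock",
      description = "Left ventricular failure (cardiogenic shock)",
      triggers = list(
        triggerSpec("ARTsys", "absolute_sustained", "below", 78,
                    duration = 300),
        triggerSpec("CVPmean", "absolute_sustained", "below", 16,
                    duration = 300),
        triggerSpec("PAPdia", "absolute_sustained", "above", 16,
                    duration = 300),
        triggerSpec("Perf", "absolute_sustained", "below", 1.2,
                    duration = 300))),
    scenarioRule("Tamponade",
      description = "Tamponade / tension pneumothorax (obstructive shock)",
      triggers = list(
        triggerSpec("ARTsys", "absolute_sustained", "below", 78,
                    duration = 180),
        triggerSpec("CVPmean", "absolute_sustained", "above", 16,
                    duration = 180),
        triggerSpec("Perf", "relative_change", "fall", 20,
                    unit = "percent", window = 180),
        triggerSpec("PAPdia", "absolute_sustained", "above", 16,
                    duration = 180))),
    scenarioRule("Hypovolemia",
      description = "Low blood pressure from hypovolemia",
      triggers = list(
        triggerSpec("ARTmean", "absolute_sustained", "below", 50,
                    duration = 300),
        triggerSpec("CVPmean", "absolute_sustained", "below", 5,
                    duration = 300),
        triggerSpec("Perf", "relative_change", "fall", 20,
                    unit = "percent", window = 120, scope = 600),
        triggerSpec("NIBPm", "absolute_sustained", "below", 55,
                    duration = 300)),
      eitherGroups = list(c("ARTmean", "NIBPm")))
  )
}

# ---- rule config serialization (YAML) --------------------------------------

.RULE_SCHEMA_VERSION <- 1L

.triggerToList <- function(tr) {
  out <- list(channel = tr@channel, kind = tr@kind,
              direction = tr@direction, threshold = tr@threshold,
              unit = tr@unit)
  if (!is.na(tr@fallback)) out$fallback <- tr@fallback
  if (!is.na(tr@duration)) out$duration_s <- tr@duration
  if (!is.na(tr@window)) out$window_s <- tr@window
  if (!is.na(tr@scope)) out$scope_s <- tr@scope
  out
}

.triggerFromList <- function(x) {
  if (is.null(x$channel) || !(x$channel %in% .channelIds()))
    stop("rule config: unknown channel '", x$channel %||% "<missing>", "'",
         call. = FALSE)
  triggerSpec(channel = x$channel, kind = x$kind,
              direction = x$direction %||% "above",
              threshold = x$threshold %||% NA_real_,
              unit = x$unit %||% "native",
              duration = x$duration_s %||% NA_real_,
              window = x$window_s %||% NA_real_,
              scope = x$scope_s %||% NA_real_,
              fallback = x$fallback %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.ruleToList <- function(rule) {
  list(name = rule@name, description = rule@description,
       co_occurrence_s = rule@coOccurrence, refractory_s = rule@refractory,
       required_channels = as.list(rule@requiredChannels),
       either_groups = lapply(rule@eitherGroups, as.list),
       triggers = lapply(rule@triggers, .triggerToList))
}

.ruleFromList <- function(x) {
  trig <- x$triggers
  if (is.null(trig) || length(trig) < 1L)
    stop("rule config: rule '", x$name %||% "?",
         "' must define at least one trigger", call. = FALSE)
  if (length(trig) > 4L)
    stop("rule config: rule '", x$name %||% "?",
         "' defines ", length(trig),
         " triggers; a maximum of four is allowed", call. = FALSE)
  scenarioRule(name = x$name, description = x$description %||% "",
               triggers = lapply(trig, .triggerFromList),
               requiredChannels = if (is.null(x$required_channels)) NULL
                                  else unlist(x$required_channels),
               eitherGroups = lapply(x$either_groups %||% list(), unlist),
               coOccurrence = x$co_occurrence_s %||% 60,
               refractory = x$refractory_s %||% 300)
}

#' Serialize scenario rules to a YAML config document
#'
#' The document is deterministic (two serializations of the same rules are
#' byte-identical) and versioned with a `schema_version` field;
#' [loadRules()] inverts it exactly.
#'
#' @param rules list of [ScenarioRule-class].
#' @return A single YAML string.
#' @examples
#' cat(substr(serializeRules(builtinScenarios()[1]), 1, 200))
#' @export
serializeRules <- function(rules) {
  doc <- list(schema_version = .RULE_SCHEMA_VERSION,
              rules = lapply(rules, .ruleToList))
  yaml::as.yaml(doc, precision = 15L)
}

#' Load scenario rules from a YAML config document
#'
#' Validates every rule: unknown channel names and rules with more than four
#' triggers are rejected.
#'
#' @param text a YAML string, or omitted when `path` is given.
#' @param path path to a YAML rule file.
#' @return List of [ScenarioRule-class].
#' @export
loadRules <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  doc <- yaml::yaml.load(text)
  if (is.null(doc$rules)) return(list())
  lapply(doc$rules, .ruleFromList)
}
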