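#' @name accessors
#' @title Accessors for icualarms S4 classes
#' @description Slot accessors: `channelId`, `traceTimes`, `traceValues`,
#'   `nominalRate` for [VitalTrace-class]; `patientId`, `recordDuration`,
#'   `traces`, `getTrace`, `channels` for [PatientRecord-class];
#'   `ruleName` and `ruleTriggers` for [ScenarioRule-class].
#' @param x an object.
#' @param channel a channel id.
#' @return The corresponding slot value (`getTrace` returns a
#'   [VitalTrace-class] or `NULL`).
NULL

#' @rdname accessors
#' @export
setGeneric("channelId", function(x) standardGeneric("channelId"))
#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("nominalRate", function(x) standardGeneric("nominalRate"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("recordDuration", function(x) standardGeneric("recordDuration"))
#' @rdname accessors
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))
#' @rdname accessors
#' @export
setGeneric("getTrace", function(x, channel) standardGeneric("getTrace"))
#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname accessors
#' @export
setGeneric("ruleName", function(x) standardGeneric("ruleName"))
#' @rdname accessors
#' @export
setGeneric("ruleTriggers", function(x) standardGeneric("ruleTriggers"))

#' @rdname accessors
setMethod("channelId", "VitalTrace", function(x) x@channel)
#' @rdname accessors
setMethod("traceTimes", "VitalTrace", function(x) x@t)
#' @rdname accessors
setMethod("traceValues", "VitalTrace", function(x) x@value)
#' @rdname accessors
setMethod("nominalRate", "VitalTrace", function(x) x@rate)
#' @rdname accessors
setMethod("patientId", "PatientRecord", function(x) x@patientId)
#' @rdname accessors
setMethod("recordDuration", "PatientRecord", function(x) x@duration)
#' @rdname accessors
setMethod("traces", "PatientRecord", function(x) x@traces)
#' @rdname accessors
setMethod("getTrace", "PatientRecord", function(x, channel) {
  if (channel %in% names(x@traces)) x@traces[[channel]] else NULL
})
#' @rdname accessors
setMethod("channels", "PatientRecord", function(x) names(x@traces))
#' @rdname accessors
setMethod("ruleName", "ScenarioRule", function(x) x@name)
#' @rdname accessors
setMethod("ruleTriggers", "ScenarioRule", function(x) x@triggers)

setMethod("show", "VitalTrace", function(object) {
  v <- object@value
  n_ok <- sum(!is.na(v))
  cat(sprintf("VitalTrace %s [%s]: %d samples over %.0f s, %d missing\n",
              object@channel,
              channelInfo()$unit[match(object@channel, channelInfo()$channel)],
              length(v), diff(range(object@t)), length(v) - n_ok))
  if (n_ok)
    cat(sprintf("  range %.3g..%.3g, nominal rate %g Hz\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE), object@rate))
})

setMethod("show", "PatientRecord", function(object) {
  cat(sprintf("PatientRecord %s: %.0f s, %d channel(s)\n",
              object@patientId, object@duration, length(object@traces)))
  if (length(object@traces))
    cat("  channels:", paste(names(object@traces), collapse = ", "), "\n")
})

setMethod("show", "TriggerSpec", function(object) {
  desc <- switch(object@kind,
    absolute_sustained = sprintf("%s %s %g %s for %g s", object@channel,
      if (object@direction == "above") ">" else "<", object@threshold,
      if (object@unit == "percent") "%" else "", object@duration),
    relative_change = sprintf("%s %s %g%s within %g s", object@channel,
      if (object@direction == "rise") "+" else "-", object@threshold,
      if (object@unit == "percent") "%" else " (native units)",
      object@window),
    flag_present = sprintf("%s present for %g s", object@channel))
  cat("TriggerSpec:", desc, "\n")
  if (!is.na(object@fallback))
    cat("  fallback channel:", object@fallback, "\n")
  if (object@kind == "relative_change" && !is.na(object@scope) &&
      object@scope > object@window)
    cat("  activity scope:", object@scope, "s\n")
})

setMethod("show", "ScenarioRule", function(object) {
  cat(sprintf("ScenarioRule '%s' (%d trigger(s), co-occurrence %g s, refractory %g s)\n",
              object@name, length(object@triggers), object@coOccurrence,
              object@refractory))
  for (tr in object@triggers) show(tr)
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d patient(s) x %.0f s, seed %d\n",
              as.integer(object@nPatients), object@duration,
              as.integer(object@seed)))
  if (nrow(object@plan)) {
    cat("  plan:\n")
    print(object@plan, row.names = FALSE)
  } else cat("  plan: (none)\n")
})
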