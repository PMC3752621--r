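#' Construct a trigger specification
#'
#' @param channel channel id the trigger reads.
#' @param kind `"absolute_sustained"`, `"relative_change"` or
#'   `"flag_present"`.
#' @param direction `"above"`/`"below"` (absolute) or `"rise"`/`"fall"`
#'   (relative); ignored for flag triggers.
#' @param threshold numeric threshold. For absolute triggers, in channel
#'   units (violation is *strict*: ">110 bpm" fires at 110.01, not at 110).
#'   For relative triggers, either a percent of baseline
#'   (`unit = "percent"`) or an absolute delta in channel units
#'   (`unit = "native"`, e.g. "+30 bpm"); the change test is inclusive
#'   ("at least" the stated change).
#' @param unit `"percent"` or `"native"`.
#' @param duration persistence requirement in seconds (absolute/flag kinds).
#' @param window lookback window in seconds (relative kind).
#' @param scope optional activity scope in seconds for relative triggers
#'   written as "within W sec / S min": once satisfied at some instant, the
#'   trigger stays active for `scope - window` further seconds. Default:
#'   equal to `window` (no extension).
#' @param fallback optional interchangeable source channel ("HR (Pulse)"):
#'   used when the primary channel is absent from a record.
#' @return A [TriggerSpec-class].
#' @examples
#' triggerSpec("Pulse", "absolute_sustained", "above", 110, duration = 20)
#' triggerSpec("HR", "relative_change", "rise", 40, unit = "percent",
#'             window = 59, fallback = "Pulse")
#' @export
triggerSpec <- function(channel, kind, direction = c("above", "below",
                                                     "rise", "fall"),
                        threshold = NA_real_, unit = "native",
                        duration = NA_real_, window = NA_real_,
                        scope = NA_real_, fallback = NA_character_) {
  if (kind == "flag_present") direction <- "above"
  else direction <- match.arg(direction)
  new("TriggerSpec", channel = channel,
      fallback = as.character(fallback), kind = kind, direction = direction,
      threshold = as.numeric(threshold), unit = unit,
      duration = as.numeric(duration), window = as.numeric(window),
      scope = as.numeric(scope))
}

.assertTriggerChannel <- function(trace, spec) {
  ok <- identical(trace@channel, spec@channel) ||
    (!is.na(spec@fallback) && identical(trace@channel, spec@fallback))
  if (!ok)
    stop(sprintf("trace channel %s does not match trigger channel %s%s",
                 trace@channel, spec@channel,
                 if (is.na(spec@fallback)) "" else
                   sprintf(" (fallback %s)", spec@fallback)),
         call. = FALSE)
}

.emptyIntervals <- function() data.frame(t_on = numeric(0),
                                         t_off = numeric(0))

#' Evaluate an absolute sustained-violation trigger
#'
#' An active interval begins at the first instant `t` at which the value has
#' been strictly beyond the threshold continuously for `duration` seconds
#' ending at `t`, and ends when the violation ceases. Missing data breaks
#' continuity: a sensor gap can never contribute violation evidence.
#'
#' @param trace a [VitalTrace-class] (need not be uniform; it is resampled).
#' @param spec a [TriggerSpec-class] of kind `absolute_sustained`.
#' @param rate evaluation grid rate (samples/second).
#' @param gapTolerance carry-forward limit passed to [resampleUniform()].
#' @return data.frame with columns `t_on`, `t_off` (seconds), one row per
#'   maximal active interval.
#' @export
evalAbsoluteTrigger <- function(trace, spec, rate = 1, gapTolerance = 10) {
  stopifnot(is(spec, "TriggerSpec"), spec@kind == "absolute_sustained")
  .assertTriggerChannel(trace, spec)
  u <- resampleUniform(trace, rate = rate, gapTolerance = gapTolerance)
  viol <- if (spec@direction == "above") u@value > spec@threshold
          else u@value < spec@threshold
  .sustainedFromViolation(viol, u@t, spec@duration)
}

.sustainedFromViolation <- function(viol, times, duration) {
  runs <- .trueRuns(viol)
  if (!nrow(runs)) return(.emptyIntervals())
  t_a <- times[runs[, "start"]]
  t_b <- times[runs[, "end"]]
  keep <- (t_b - t_a) >= duration
  if (!any(keep)) return(.emptyIntervals())
  data.frame(t_on = t_a[keep] + duration, t_off = t_b[keep])
}

#' Evaluate a rhythm-flag trigger
#'
#' Active while a 0/1 annotation channel (e.g. the monitor's ventricular
#' tachycardia call) has been 1 continuously for `duration` seconds.
#'
#' @inheritParams evalAbsoluteTrigger
#' @param spec a [TriggerSpec-class] of kind `flag_present`.
#' @return data.frame with columns `t_on`, `t_off`.
#' @export
evalFlagTrigger <- function(trace, spec, rate = 1, gapTolerance = 10) {
  stopifnot(is(spec, "TriggerSpec"), spec@kind == "flag_present")
  .assertTriggerChannel(trace, spec)
  u <- resampleUniform(trace, rate = rate, gapTolerance = gapTolerance)
  .sustainedFromViolation(u@value == 1, u@t, spec@duration)
}

#' Evaluate a relative-change trigger
#'
#' The trigger is satisfied at instant `t` if, for some lag in
#' `(0, window]`, the smoothed value at `t` differs from the smoothed
#' baseline at `t - lag` by at least the stated percent (or absolute delta)
#' in the trigger's direction. Smoothing is the trailing 10-s median of
#' [baselineValue()], so single-sample spikes neither trigger a change nor
#' corrupt the baseline. Maximal satisfied intervals are returned; if the
#' trigger declares a `scope` beyond its window ("within 120 sec / 10 min"),
#' each satisfied instant keeps the trigger active for `scope - window`
#' further seconds.
#'
#' @inheritParams evalAbsoluteTrigger
#' @param spec a [TriggerSpec-class] of kind `relative_change`.
#' @param smoothing trailing median window in seconds (default 10).
#' @return data.frame with columns `t_on`, `t_off`.
#' @export
evalRelativeTrigger <- function(trace, spec, rate = 1, gapTolerance = 10,
                                smoothing = 10) {
  stopifnot(is(spec, "TriggerSpec"), spec@kind == "relative_change")
  .assertTriggerChannel(trace, spec)
  span <- trace@t[length(trace@t)] - trace@t[1]
  if (spec@window >= span) {
    warning("relative trigger window (", spec@window,
            " s) is not shorter than the record span (", span,
            " s); no evaluation possible", call. = FALSE)
    return(.emptyIntervals())
  }
  u <- resampleUniform(trace, rate = rate, gapTolerance = gapTolerance)
  s <- .rollMedianRight(u@value, as.integer(round(smoothing * rate)))
  w <- as.integer(round(spec@window * rate))
  sat <- .relativeSatisfied(s, w, spec)
  if (!is.na(spec@scope) && spec@scope > spec@window) {
    ext <- as.integer(round((spec@scope - spec@window) * rate))
    sat <- .rollMaxRight(as.numeric(sat), ext + 1L) >= 1
    sat[is.na(sat)] <- FALSE
  }
  runs <- .trueRuns(sat)
  if (!nrow(runs)) return(.emptyIntervals())
  data.frame(t_on = u@t[runs[, "start"]], t_off = u@t[runs[, "end"]])
}

# Per-sample satisfaction of a relative trigger against the extreme of the
# smoothed series over the previous `w` samples. Comparing against the
# windowed min (rise) / max (fall) is equivalent to testing every lag,
# because the comparison is monotone in the baseline (percent thresholds
# are confined to (0, 100], keeping the scale factor positive). Percent
# changes are undefined against a non-positive baseline, so those samples
# are masked out of the reference rather than collapsing the window.
.relativeSatisfied <- function(s, w, spec) {
  base <- s
  if (spec@unit == "percent") base[!is.na(base) & base <= 0] <- NA_real_
  if (spec@direction == "rise") {
    ref <- .rollExtremePrev(base, w, max = FALSE)
    if (spec@unit == "percent") {
      sat <- !is.na(ref) & !is.na(s) & s >= ref * (1 + spec@threshold / 100)
    } else {
      sat <- !is.na(ref) & !is.na(s) & s >= ref + spec@threshold
    }
  } else {
    ref <- .rollExtremePrev(base, w, max = TRUE)
    if (spec@unit == "percent") {
      sat <- !is.na(ref) & !is.na(s) & s <= ref * (1 - spec@threshold / 100)
    } else {
      sat <- !is.na(ref) & !is.na(s) & s <= ref - spec@threshold
    }
  }
  sat
}

#' Evaluate any trigger kind
#'
#' Dispatches on `spec@kind` to [evalAbsoluteTrigger()],
#' [evalRelativeTrigger()] or [evalFlagTrigger()].
#'
#' @inheritParams evalRelativeTrigger
#' @return data.frame with columns `t_on`, `t_off`.
#' @export
evalTrigger <- function(trace, spec, rate = 1, gapTolerance = 10,
                        smoothing = 10) {
  switch(spec@kind,
    absolute_sustained = evalAbsoluteTrigger(trace, spec, rate, gapTolerance),
    relative_change = evalRelativeTrigger(trace, spec, rate, gapTolerance,
                                          smoothing),
    flag_present = evalFlagTrigger(trace, spec, rate, gapTolerance),
    stop("unknown trigger kind: ", spec@kind, call. = FALSE))
}
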