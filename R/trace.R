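#' Construct a validated vital-sign trace
#'
#' @param channel channel id (see [channelInfo()]).
#' @param t numeric timestamps in seconds from record start, strictly
#'   increasing.
#' @param value numeric values in the channel's native units; `NA` = missing.
#' @param rate nominal sampling rate in samples/second (default 1 Hz, the
#'   typical numerics export rate of bedside monitors).
#' @return A [VitalTrace-class].
#' @examples
#' makeTrace("HR", t = 0:5, value = c(80, 81, 80, NA, 82, 81))
#' @export
makeTrace <- function(channel, t, value, rate = 1) {
  .assertChannel(channel)
  t <- as.numeric(t)
  value <- as.numeric(value)
  if (length(t) == 0L) stop("samples must be non-empty", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing (ordering error)",
         call. = FALSE)
  rng <- .channelRange(channel)
  v <- value[!is.na(value)]
  if (length(v) && (any(v < rng[1]) || any(v > rng[2])))
    stop(sprintf("value out of carrier range [%g, %g] for channel %s",
                 rng[1], rng[2], channel), call. = FALSE)
  new("VitalTrace", channel = channel, t = t, value = value, rate = rate)
}

# Values of a trace carried onto an arbitrary time grid by
# last-observation-carried-forward, up to gapTolerance seconds; NA beyond the
# tolerance and before the first sample.
.gridValues <- function(trace, times, gapTolerance = 10) {
  idx <- findInterval(times, trace@t)
  out <- rep(NA_real_, length(times))
  has <- idx >= 1L
  out[has] <- trace@value[idx[has]]
  stale <- has & (times - trace@t[pmax(idx, 1L)] > gapTolerance)
  out[stale] <- NA_real_
  out
}

#' Resample a trace onto a uniform grid
#'
#' Produces a uniform grid covering the trace span at the requested rate.
#' Values are carried forward from the last sample at or before each grid
#' point, but only up to `gapTolerance` seconds: beyond that the grid point
#' is missing rather than stale, so that dropped sensors cannot fabricate
#' sustained-violation evidence.
#'
#' @param trace a [VitalTrace-class].
#' @param rate target rate in samples/second.
#' @param gapTolerance carry-forward limit in seconds (default 10).
#' @return A [VitalTrace-class] on the uniform grid.
#' @examples
#' tr <- makeTrace("HR", t = c(0, 5), value = c(80, 90))
#' traceValues(resampleUniform(tr, 1))
#' @export
resampleUniform <- function(trace, rate = 1, gapTolerance = 10) {
  stopifnot(is(trace, "VitalTrace"))
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  t0 <- trace@t[1]
  t1 <- trace@t[length(trace@t)]
  grid <- seq(t0, t1, by = 1 / rate)
  vals <- .gridValues(trace, grid, gapTolerance)
  new("VitalTrace", channel = trace@channel, t = grid, value = vals,
      rate = rate)
}

#' Smoothed baseline value at a time point
#'
#' The median of non-missing samples in the trailing window
#' `[t - smoothing, t]`. The median resists single-sample spikes, so relative
#' triggers referenced to it do not fire on isolated artifacts.
#'
#' @param trace a [VitalTrace-class].
#' @param t time in seconds.
#' @param smoothing window length in seconds (> 0, default 10).
#' @return The median value, or `NA` if no non-missing sample lies in the
#'   window.
#' @export
baselineValue <- function(trace, t, smoothing = 10) {
  stopifnot(is(trace, "VitalTrace"))
  if (smoothing <= 0) stop("smoothing must be > 0", call. = FALSE)
  sel <- trace@t >= t - smoothing & trace@t <= t
  v <- trace@value[sel]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  stats::median(v)
}

#' Missing-data intervals of a trace
#'
#' Maximal intervals where the uniform-grid version of the trace is missing.
#' Intervals are half-open `[t_start, t_end)` in grid time: a gap covering
#' grid points 10..19 at 1 Hz is reported as `(10, 20)`.
#'
#' @param trace a [VitalTrace-class].
#' @param rate grid rate in samples/second.
#' @param gapTolerance carry-forward limit in seconds.
#' @return A data.frame with columns `t_start`, `t_end`, sorted and
#'   non-overlapping; zero rows if fully observed.
#' @export
maskGaps <- function(trace, rate = 1, gapTolerance = 10) {
  u <- resampleUniform(trace, rate = rate, gapTolerance = gapTolerance)
  runs <- .trueRuns(is.na(u@value))
  if (!nrow(runs))
    return(data.frame(t_start = numeric(0), t_end = numeric(0)))
  data.frame(t_start = u@t[runs[, "start"]],
             t_end = u@t[runs[, "end"]] + 1 / rate)
}

#' Screen physically implausible values from a trace
#'
#' Sets values outside `[low, high]` to missing and reports how many were
#' replaced. This is the optional artifact screen that re-examines a
#' parameter already consumed by a trigger (e.g. excluding CVP readings
#' outside -5..40 mmHg); it is unavailable in compatibility mode, where each
#' parameter may be consulted at most once per rule.
#'
#' @param trace a [VitalTrace-class].
#' @param low,high plausibility limits in channel units (`low < high`).
#' @return A list with `trace` (filtered [VitalTrace-class]) and `replaced`
#'   (count of values set to missing).
#' @examples
#' tr <- makeTrace("CVPmean", t = 0:2, value = c(8, 200, 9))
#' plausibilityFilter(tr, -5, 40)$replaced
#' @export
plausibilityFilter <- function(trace, low, high) {
  stopifnot(is(trace, "VitalTrace"))
  if (!(low < high)) stop("low must be < high", call. = FALSE)
  v <- trace@value
  bad <- !is.na(v) & (v < low | v > high)
  v[bad] <- NA_real_
  out <- new("VitalTrace", channel = trace@channel, t = trace@t, value = v,
             rate = trace@rate)
  list(trace = out, replaced = sum(bad))
}
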