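# Independent brute-force oracles for trigger semantics, plus small fixture
# builders. The oracles evaluate the definitions sample by sample, with no
# shared code paths with the package's vectorized evaluators.

# Active instants of an absolute sustained-violation trigger by direct scan:
# active at t iff every grid sample in [t - duration, t] strictly violates
# the threshold (missing breaks continuity; no evidence before the trace
# holds a full window).
oracleAbsoluteIntervals <- function(values, times, threshold, direction,
                                    duration) {
  viol <- if (direction == "above") values > threshold
          else values < threshold
  viol[is.na(viol)] <- FALSE
  n <- length(values)
  active <- logical(n)
  for (i in seq_len(n)) {
    if (times[i] - duration < times[1]) next
    win <- which(times >= times[i] - duration & times <= times[i])
    active[i] <- all(viol[win])
  }
  runsToIntervals(active, times)
}

# Active instants of a relative-change trigger: trailing-median smoothing
# computed directly, then every lag in (0, window] tested.
oracleRelativeIntervals <- function(values, times, threshold, unit,
                                    direction, window, smoothing = 10,
                                    scope = NA) {
  n <- length(values)
  s <- vapply(seq_len(n), function(i) {
    w <- values[times >= times[i] - smoothing & times <= times[i]]
    w <- w[!is.na(w)]
    if (!length(w)) NA_real_ else stats::median(w)
  }, 0)
  sat <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(s[i])) next
    js <- which(times >= times[i] - window & times < times[i])
    for (j in js) {
      b <- s[j]
      if (is.na(b)) next
      ok <- if (unit == "percent") {
        if (b <= 0) FALSE
        else if (direction == "rise") s[i] >= b * (1 + threshold / 100)
        else s[i] <= b * (1 - threshold / 100)
      } else {
        if (direction == "rise") s[i] >= b + threshold
        else s[i] <= b - threshold
      }
      if (ok) { sat[i] <- TRUE; break }
    }
  }
  if (!is.na(scope) && scope > window) {
    ext <- scope - window
    dil <- logical(n)
    for (i in which(sat)) dil[times >= times[i] & times <= times[i] + ext &
                               seq_len(n) >= i] <- TRUE
    sat <- sat | dil
  }
  runsToIntervals(sat, times)
}

runsToIntervals <- function(active, times) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(t_on = times[starts[keep]], t_off = times[ends[keep]])
}

# Random 1 Hz test trace: AR-style wander with occasional spikes and
# missing stretches, clipped into the HR carrier range.
randomHrTrace <- function(n) {
  v <- 80 + cumsum(stats::rnorm(n, 0, 2))
  if (n > 4 && stats::runif(1) < 0.5) {
    k <- sample(n, max(1, n %/% 20))
    v[k] <- v[k] + sample(c(-60, 60), length(k), replace = TRUE)
  }
  if (n > 10 && stats::runif(1) < 0.4) {
    g0 <- sample(n - 5, 1)
    v[g0:min(n, g0 + sample(8, 1))] <- NA
  }
  v <- pmin(pmax(v, 0), 350)
  makeTrace("HR", 0:(n - 1), v)
}

# A hand-built SVT-like episode record: HR/Pulse ramp 80 -> target and
# ARTsys ramps 120 -> target over 30 s starting at t0, holding for hold_s.
svtEpisodeRecord <- function(duration = 1200, t0 = 300, hr_target = 125,
                             art_target = 95, hold_s = 300) {
  tt <- 0:(duration - 1)
  ramp <- function(base, target) {
    v <- rep(base, duration)
    ri <- which(tt >= t0 & tt < t0 + 30)
    v[ri] <- base + (target - base) * seq_along(ri) / 30
    hi <- which(tt >= t0 + 30 & tt < t0 + 30 + hold_s)
    v[hi] <- target
    v
  }
  patientRecord("ep1", duration, list(
    makeTrace("HR", tt, ramp(80, hr_target)),
    makeTrace("Pulse", tt, ramp(80, hr_target)),
    makeTrace("ARTsys", tt, ramp(120, art_target))))
}
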