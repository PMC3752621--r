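test_that("absolute sustained trigger follows persistence semantics", {
  spec <- triggerSpec("Pulse", "absolute_sustained", "above", 110,
                      duration = 20)

  # constant violation: interval starts once 20 s of evidence accumulated
  tr <- makeTrace("Pulse", 0:60, rep(120, 61))
  expect_equal(evalAbsoluteTrigger(tr, spec),
               data.frame(t_on = 20, t_off = 60))

  # never violates
  low <- makeTrace("ARTsys", 0:599, rep(90, 600))
  bspec <- triggerSpec("ARTsys", "absolute_sustained", "below", 78,
                       duration = 300)
  expect_equal(nrow(evalAbsoluteTrigger(low, bspec)), 0)

  # square wave 10 s above / 10 s below: violation never persists 20 s
  sq <- makeTrace("Pulse", 0:199, rep(c(rep(120, 10), rep(90, 10)), 10))
  expect_equal(nrow(evalAbsoluteTrigger(sq, spec)), 0)
  expect_equal(evalAbsoluteTrigger(sq, spec),
               oracleAbsoluteIntervals(traceValues(sq), traceTimes(sq),
                                       110, "above", 20))

  # strict inequality: sitting exactly at the threshold never fires
  at <- makeTrace("Pulse", 0:60, rep(110, 61))
  expect_equal(nrow(evalAbsoluteTrigger(at, spec)), 0)
  above <- makeTrace("Pulse", 0:60, rep(110.01, 61))
  expect_equal(nrow(evalAbsoluteTrigger(above, spec)), 1)

  # missing data breaks continuity
  v <- rep(120, 61); v[30] <- NA
  gappy <- makeTrace("Pulse", 0:60, v)
  got <- evalAbsoluteTrigger(gappy, spec)
  expect_equal(got, oracleAbsoluteIntervals(v, 0:60, 110, "above", 20))

  # channel mismatch is a configuration error
  expect_error(evalAbsoluteTrigger(makeTrace("HR", 0:5, rep(120, 6)), spec),
               "does not match")
})

test_that("relative change trigger detects rises and falls within window", {
  rise40 <- triggerSpec("HR", "relative_change", "rise", 40,
                        unit = "percent", window = 59)

  # ramp 80 -> 120 over 30 s: 120 >= 1.4 * 80 at lag <= 59 s
  v <- c(rep(80, 100), 80 + 40 * (1:30) / 30, rep(120, 100))
  ramp <- makeTrace("HR", seq_along(v) - 1, v)
  expect_gt(nrow(evalRelativeTrigger(ramp, rise40)), 0)

  # constant trace: no change, no trigger
  const <- makeTrace("HR", 0:299, rep(80, 300))
  expect_equal(nrow(evalRelativeTrigger(const, rise40)), 0)

  # "+30 bpm within 20 s" boundary: a step to +29 never fires, +31 does
  d30 <- triggerSpec("HR", "relative_change", "rise", 30, unit = "native",
                     window = 20)
  step <- function(hi) makeTrace("HR", 0:199,
                                 c(rep(80, 100), rep(hi, 100)))
  expect_equal(nrow(evalRelativeTrigger(step(109), d30)), 0)
  expect_gt(nrow(evalRelativeTrigger(step(111), d30)), 0)

  # window not shorter than the record span: empty result with a warning
  short <- makeTrace("HR", 0:30, rep(80, 31))
  expect_warning(out <- evalRelativeTrigger(short, rise40), "window")
  expect_equal(nrow(out), 0)
})

test_that("single-trigger evaluators agree exactly with brute-force scans", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(30:250, 1)
    tr <- randomHrTrace(n)
    v <- traceValues(tr); tt <- traceTimes(tr)

    thr <- stats::runif(1, 60, 130)
    dur <- sample(3:40, 1)
    dirn <- sample(c("above", "below"), 1)
    aspec <- triggerSpec("HR", "absolute_sustained", dirn, thr,
                         duration = dur)
    expect_equal(evalAbsoluteTrigger(tr, aspec),
                 oracleAbsoluteIntervals(v, tt, thr, dirn, dur))

    w <- sample(5:60, 1)
    if (w < n - 1) {
      unit <- sample(c("percent", "native"), 1)
      rthr <- if (unit == "percent") stats::runif(1, 5, 60)
              else stats::runif(1, 5, 40)
      rdir <- sample(c("rise", "fall"), 1)
      rspec <- triggerSpec("HR", "relative_change", rdir, rthr,
                           unit = unit, window = w)
      expect_equal(evalRelativeTrigger(tr, rspec),
                   oracleRelativeIntervals(v, tt, rthr, unit, rdir, w))
    }
  }
})

test_that("relative trigger scope extends activity beyond the window", {
  # fall completes within 120 s; with a 600 s scope the trigger stays
  # active long after the lookback has passed the change
  v <- c(rep(2, 200), 2 - 1 * (1:30) / 30, rep(1, 800))
  tr <- makeTrace("Perf", seq_along(v) - 1, v)
  plain <- triggerSpec("Perf", "relative_change", "fall", 20,
                       unit = "percent", window = 120)
  scoped <- triggerSpec("Perf", "relative_change", "fall", 20,
                        unit = "percent", window = 120, scope = 600)
  iv_plain <- evalRelativeTrigger(tr, plain)
  iv_scoped <- evalRelativeTrigger(tr, scoped)
  expect_gt(nrow(iv_plain), 0)
  expect_equal(max(iv_scoped$t_off), max(iv_plain$t_off) + 480)
  expect_equal(iv_scoped,
               oracleRelativeIntervals(v, traceTimes(tr), 20, "percent",
                                       "fall", 120, scope = 600))
})

test_that("flag trigger requires sustained annotation", {
  fspec <- triggerSpec("VtachFlag", "flag_present", threshold = 1,
                       duration = 5)
  v <- rep(0, 60); v[21:41] <- 1                          # t in [20, 40]
  tr <- makeTrace("VtachFlag", 0:59, v)
  expect_equal(evalFlagTrigger(tr, fspec),
               data.frame(t_on = 25, t_off = 40))
  short <- rep(0, 60); short[20:23] <- 1                  # only 3 s of flag
  expect_equal(nrow(evalFlagTrigger(makeTrace("VtachFlag", 0:59, short),
                                    fspec)), 0)
})

test_that("raising a threshold or extending persistence never adds alarms", {
  set.seed(55)
  for (rep in 1:15) {
    tr <- randomHrTrace(300)
    thr <- stats::runif(1, 70, 110)
    dur <- sample(5:30, 1)
    rec <- patientRecord("m1", 300, list(tr))
    nAlarms <- function(threshold, duration) {
      rule <- scenarioRule("mono", list(
        triggerSpec("HR", "absolute_sustained", "above", threshold,
                    duration = duration)), refractory = 30)
      nrow(evalScenario(rec, rule))
    }
    base <- nAlarms(thr, dur)
    expect_lte(nAlarms(thr + 10, dur), base)
    expect_lte(nAlarms(thr, dur + 15), base)
  }
})
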