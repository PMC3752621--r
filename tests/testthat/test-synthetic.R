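test_that("simulation is deterministic and honours the plan bookkeeping", {
  plan <- data.frame(kind = c("svt_bp", "artifact_motion"),
                     count = c(2, 1), margin = c(0.1, 0))
  spec <- cohortSpec(nPatients = 2, duration = 7200, plan = plan, seed = 5)
  s1 <- simulateCohort(spec)
  s2 <- simulateCohort(spec)
  expect_identical(s1$truth, s2$truth)
  for (i in seq_along(s1$records))
    expect_identical(traceValues(getTrace(s1$records[[i]], "HR")),
                     traceValues(getTrace(s2$records[[i]], "HR")))

  # plan expansion: 2 + 1 = 3 truth events, correct kinds
  expect_equal(nrow(s1$truth), 3)
  expect_equal(sort(table(s1$truth$kind), decreasing = TRUE),
               sort(table(c("svt_bp", "svt_bp", "artifact_motion")),
                    decreasing = TRUE))
  expect_true(all(s1$truth$t_start < s1$truth$t_end))

  # different seed, different noise
  s3 <- simulateCohort(cohortSpec(nPatients = 2, duration = 7200,
                                  plan = plan, seed = 6))
  expect_false(identical(traceValues(getTrace(s1$records[[1]], "HR")),
                         traceValues(getTrace(s3$records[[1]], "HR"))))
})

test_that("baseline noise model matches its stated moments", {
  spec <- cohortSpec(nPatients = 1, duration = 36000, seed = 17)
  rec <- simulateCohort(spec)$records[[1]]
  nm <- defaultNoiseModel()
  for (ch in c("HR", "ARTsys", "CVPmean", "Perf")) {
    v <- traceValues(getTrace(rec, ch))
    m <- nm$mean[nm$channel == ch]; s <- nm$sd[nm$channel == ch]
    expect_lt(abs(mean(v) - m), 3 * s / sqrt(36000 / 40))  # AR(1) ESS
    expect_lt(abs(stats::sd(v) - s) / s, 0.35)
    r1 <- stats::cor(v[-1], v[-length(v)])
    expect_gt(r1, 0.9)
  }
  # Pulse tracks HR sample for sample (same physiology, different sensor)
  hr <- traceValues(getTrace(rec, "HR"))
  pulse <- traceValues(getTrace(rec, "Pulse"))
  expect_lt(max(abs(hr - pulse)), 5)
})

test_that("quiet records produce no alarms from any built-in rule", {
  # false-alarm floor of the noise model: 10 patient-days, empty plan
  spec <- cohortSpec(nPatients = 10, duration = 86400, seed = 23)
  sim <- simulateCohort(spec)
  det <- detectAlarms(sim$records)
  expect_equal(nrow(det$alarms), 0)
  expect_true(all(det$eligibility$eligible))
})

test_that("episode injection hits the documented plateau arithmetic", {
  spec <- cohortSpec(nPatients = 1, duration = 4000, seed = 41)
  rec <- simulateCohort(spec)$records[[1]]
  res <- injectEpisode(rec, "lv_shock", t0 = 1000, margin = 0.1)
  r2 <- res$record
  mid <- function(ch) traceValues(getTrace(r2, ch))[1200]   # inside hold
  expect_equal(mid("ARTsys"), 78 * 0.9)                      # 70.2
  expect_equal(mid("CVPmean"), 16 * 0.9)                     # 14.4
  expect_equal(mid("PAPdia"), 16 * 1.1)                      # 17.6
  expect_equal(mid("Perf"), 1.2 * 0.9)                       # 1.08
  expect_equal(res$truth$t_end - res$truth$t_start, 30 + 360 + 120)

  # tamponade: CVP above, Perf falls ~22% from its local baseline
  res2 <- injectEpisode(rec, "tamponade", t0 = 2500, margin = 0.1)
  v <- traceValues(getTrace(res2$record, "CVPmean"))[2700]
  expect_equal(v, 16 * 1.1)
  perf0 <- median(traceValues(getTrace(rec, "Perf"))[2491:2500])
  perf1 <- traceValues(getTrace(res2$record, "Perf"))[2700]
  expect_equal(perf1 / perf0, 1 - 0.20 * 1.1, tolerance = 1e-10)

  expect_error(injectEpisode(rec, "afib", 100, 0.1), "unknown episode")
  expect_error(injectEpisode(rec, "lv_shock", 3900, 0.1), "scheduling")
})

test_that("detectable episodes alarm inside their interval; sub-threshold never", {
  plan <- data.frame(kind = rep(c("svt_bp", "vtach_bp", "lv_shock",
                                  "tamponade", "hypovolemia"), 2),
                     count = 1, margin = rep(c(0.1, -0.1), each = 5))
  spec <- cohortSpec(nPatients = 2, duration = 14400, plan = plan,
                     seed = 19)
  sim <- simulateCohort(spec)
  det <- detectAlarms(sim$records)
  for (j in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[j, ]
    own <- det$alarms$scenario == scenarioForKind(tr$kind) &
      det$alarms$patient_id == tr$patient_id &
      det$alarms$t_fire >= tr$t_start - 60 &
      det$alarms$t_fire <= tr$t_end + 60
    if (tr$intended_detectable) expect_gte(sum(own), 1)
    else expect_equal(sum(own), 0)
  }
})

test_that("artifact injections reproduce their failure modes", {
  spec <- cohortSpec(nPatients = 1, duration = 5000, seed = 57)
  rec <- simulateCohort(spec)$records[[1]]

  # plain CVP spike: reading pegged at 200, nothing else touched
  a1 <- injectArtifact(rec, "artifact_cvp_spike", 1000)
  expect_equal(traceValues(getTrace(a1$record, "CVPmean"))[1100], 200)
  expect_identical(traceValues(getTrace(a1$record, "ARTsys")),
                   traceValues(getTrace(rec, "ARTsys")))
  expect_false(a1$truth$intended_detectable)
  # ... and fires nothing: the conjunction needs the other sensors
  expect_equal(nrow(detectAlarms(a1$record)$alarms), 0)

  # provoking variant fires tamponade; the CVP screen disarms it
  a2 <- injectArtifact(rec, "artifact_cvp_spike", 1000,
                       params = list(provoke = TRUE))
  expect_true(a2$truth$intended_detectable)
  d_on <- detectAlarms(a2$record, compatibilityMode = TRUE)
  expect_equal(unique(d_on$alarms$scenario), "Tamponade")
  d_off <- detectAlarms(a2$record,
                        plausibility = list(CVPmean = c(-5, 40)))
  expect_equal(nrow(d_off$alarms), 0)

  # leveling error offsets one pressure channel by a constant
  a3 <- injectArtifact(rec, "artifact_level_error", 2500,
                       params = list(channel = "CVPmean", offset = 20,
                                     duration = 400))
  delta <- traceValues(getTrace(a3$record, "CVPmean"))[2600] -
    traceValues(getTrace(rec, "CVPmean"))[2600]
  expect_equal(delta, 20)
  expect_equal(nrow(detectAlarms(a3$record)$alarms), 0)

  # motion: ECG-side disturbance with the pulse oximeter at baseline
  a4 <- injectArtifact(rec, "artifact_motion", 3500)
  expect_gt(max(traceValues(getTrace(a4$record, "HR"))[3501:3560]), 140)
  expect_identical(traceValues(getTrace(a4$record, "Pulse")),
                   traceValues(getTrace(rec, "Pulse")))
  expect_equal(max(traceValues(getTrace(a4$record, "VtachFlag"))), 1)
  expect_equal(nrow(detectAlarms(a4$record)$alarms), 0)

  # sensor off blanks the requested channels
  a5 <- injectArtifact(rec, "sensor_off", 4000,
                       params = list(channels = "HR", duration = 200))
  expect_true(all(is.na(traceValues(getTrace(a5$record, "HR"))[4010:4190])))

  expect_error(injectArtifact(rec, "artifact_unknown", 100), "unknown")
})

test_that("a sensor-off interval over an episode yields a missed detection", {
  spec <- cohortSpec(nPatients = 1, duration = 4000, seed = 9)
  sim <- simulatePatient(spec, seed = 99, patientId = "p1",
                         planItems = data.frame(kind = "svt_bp",
                                                margin = 0.1))
  tr <- sim$truth
  off <- injectArtifact(sim$record, "sensor_off", t0 = tr$t_start - 10,
                        params = list(channels = "HR",
                                      duration = tr$t_end - tr$t_start + 80))
  det <- detectAlarms(off$record)
  expect_equal(nrow(det$alarms), 0)
  truth <- rbind(tr, cbind(patient_id = "p1", off$truth))
  cls <- classifyEvents(matchAlarms(det$alarms, truth))
  expect_equal(cls$label[cls$truth_kind == "svt_bp"], "FN_SENS_OFF")
})
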