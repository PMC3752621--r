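mkAlarm <- function(patient, scenario, t) {
  a <- data.frame(patient_id = patient, scenario = scenario, t_fire = t,
                  stringsAsFactors = FALSE)
  for (k in 1:4) {
    a[[sprintf("trigger_%d_on", k)]] <- NA_real_
    a[[sprintf("trigger_%d_off", k)]] <- NA_real_
  }
  a
}

mkTruth <- function(patient, kind, t0, t1, detectable = TRUE) {
  data.frame(patient_id = patient, kind = kind, t_start = t0, t_end = t1,
             intended_detectable = detectable, stringsAsFactors = FALSE)
}

test_that("alarm-truth matching uses interval containment with tolerance", {
  truth <- mkTruth("p1", "svt_bp", 90, 200)
  m <- matchAlarms(mkAlarm("p1", "SVT+BP", 100), truth, tolerance = 60)
  expect_equal(m$alarms$truth_row, 1L)
  expect_true(m$truth$matched)

  # tolerance extends the interval on both sides
  m2 <- matchAlarms(mkAlarm("p1", "SVT+BP", 45), truth, tolerance = 60)
  expect_equal(m2$alarms$truth_row, 1L)
  m3 <- matchAlarms(mkAlarm("p1", "SVT+BP", 20), truth, tolerance = 60)
  expect_true(is.na(m3$alarms$truth_row))

  # scenario and patient must agree for clinical truths
  m4 <- matchAlarms(mkAlarm("p1", "LV shock", 100), truth, tolerance = 60)
  expect_true(is.na(m4$alarms$truth_row))
  m5 <- matchAlarms(mkAlarm("p2", "SVT+BP", 100), truth, tolerance = 60)
  expect_true(is.na(m5$alarms$truth_row))

  # artifact truths absorb alarms of any scenario
  art <- mkTruth("p1", "artifact_cvp_spike", 90, 200, FALSE)
  m6 <- matchAlarms(mkAlarm("p1", "Tamponade", 100), art, tolerance = 60)
  expect_equal(m6$alarms$truth_kind, "artifact_cvp_spike")

  # one truth event may absorb several refractory-separated alarms
  two <- rbind(mkAlarm("p1", "SVT+BP", 100), mkAlarm("p1", "SVT+BP", 180))
  m7 <- matchAlarms(two, truth, tolerance = 60)
  expect_equal(m7$alarms$truth_row, c(1L, 1L))
  expect_equal(m7$truth$n_alarms, 2L)
})

test_that("event classification implements the taxonomy", {
  truth <- rbind(
    mkTruth("p1", "svt_bp", 1000, 1200),              # real event, alarmed
    mkTruth("p1", "lv_shock", 3000, 3500),            # alarmed before onset
    mkTruth("p1", "artifact_cvp_spike", 5000, 5300, FALSE),
    mkTruth("p1", "confounder", 7000, 7400, FALSE),
    mkTruth("p1", "tamponade", 9000, 9400),           # missed, sensors on
    mkTruth("p1", "svt_bp", 11000, 11200),            # missed, sensor off
    mkTruth("p1", "sensor_off", 10950, 11300, FALSE),
    mkTruth("p1", "hypovolemia", 13000, 13500, FALSE) # sub-threshold
  )
  alarms <- rbind(
    mkAlarm("p1", "SVT+BP", 1050),
    mkAlarm("p1", "SVT+BP", 1150),                    # same event, re-arm
    mkAlarm("p1", "LV shock", 2950),                  # early, within tol
    mkAlarm("p1", "Tamponade", 5100),                 # artifact-driven
    mkAlarm("p1", "Vtach+BP", 7100),                  # confounded context
    mkAlarm("p1", "Hypovolemia", 20000)               # no correlate
  )
  cls <- classifyEvents(matchAlarms(alarms, truth, tolerance = 60))

  lbl <- function(kind) cls$label[!is.na(cls$truth_kind) &
                                    cls$truth_kind == kind]
  expect_equal(lbl("svt_bp"), c("TPRE", "FN_SENS_OFF"))
  expect_equal(lbl("lv_shock"), "TP_PREDICT")
  expect_equal(lbl("artifact_cvp_spike"), "FP_ART")
  expect_equal(lbl("confounder"), "FP_INS_DEF")
  expect_equal(lbl("tamponade"), "FN_TH")
  expect_equal(lbl("hypovolemia"), "FN_NO_TH")
  expect_equal(cls$label[is.na(cls$truth_kind)], "FP_ART")

  # two alarms inside one truth interval count as one event by default
  expect_equal(sum(cls$truth_kind == "svt_bp" & cls$label == "TPRE",
                   na.rm = TRUE), 1)
  expect_equal(cls$n_alarms[cls$label == "TPRE"], 2L)
  # ... but alarm-level counting is available
  cls_a <- classifyEvents(matchAlarms(alarms, truth, tolerance = 60),
                          alarmCounting = "alarms")
  expect_equal(sum(cls_a$truth_kind == "svt_bp" & cls_a$label == "TPRE",
                   na.rm = TRUE), 2)

  # partition: every alarm is in exactly one alarm-side event; every truth
  # is matched or yields exactly one FN label
  alarm_side <- cls$label %in% c("TPRE", "TP_PREDICT", "FP_ART",
                                 "FP_INS_DEF")
  expect_equal(sum(cls$n_alarms[alarm_side]), nrow(alarms))
  fn_side <- cls$label %in% c("FN_TH", "FN_NO_TH", "FN_SENS_OFF")
  expect_equal(sum(fn_side), 3)

  # input order does not matter
  set.seed(2)
  cls_p <- classifyEvents(matchAlarms(
    alarms[sample(nrow(alarms)), ], truth[sample(nrow(truth)), ],
    tolerance = 60))
  expect_equal(table(cls_p$label), table(cls$label))
})

test_that("PPV arithmetic matches its definition", {
  r1 <- metricsFromCounts("LV shock", tp = 34, fpArt = 8, fpInsDef = 0)
  expect_equal(r1$ppv, 34 / 42)
  expect_equal(r1$n_events, 42)

  r2 <- metricsFromCounts("Vtach+BP", tp = 1, fpArt = 0)
  expect_equal(r2$ppv, 1.0)

  r3 <- metricsFromCounts("quiet", tp = 0, fpArt = 0)
  expect_true(is.na(r3$ppv))

  # computeMetrics counts labels the same way
  cls <- data.frame(
    patient_id = "p1", scenario = "SVT+BP",
    label = c("TPRE", "TPRE", "TP_PREDICT", "FP_ART", "FP_INS_DEF",
              "FN_TH"),
    t = 1:6, truth_kind = NA, n_alarms = 1, rationale = "")
  row <- computeMetrics(cls, "SVT+BP")
  expect_equal(row$tp, 3)
  expect_equal(row$fp_art, 1)
  expect_equal(row$fp_ins_def, 1)
  expect_equal(row$fn, 1)
  expect_equal(row$ppv, 3 / 5)
})

test_that("cohort summary aggregates rows and counts quiet intervals", {
  rows <- rbind(
    metricsFromCounts("SVT+BP", 171, 17, 22, 9),
    metricsFromCounts("Vtach+BP", 1, 0, 0, 0),
    metricsFromCounts("LV shock", 34, 8, 0, 1))
  s <- summarizeCohort(rows)
  expect_equal(s$overall_fp_fraction,
               (17 + 22 + 8) / (210 + 1 + 42))
  expect_equal(nrow(s$table), 3)

  # zero-FP degenerate case
  s0 <- summarizeCohort(metricsFromCounts("SVT+BP", 5, 0))
  expect_equal(s0$overall_fp_fraction, 0)

  # time-interval accounting over patient-days
  recs <- list(
    patientRecord("p1", 86400, list(makeTrace("HR", 0:10, rep(80, 11)))),
    patientRecord("p2", 86400, list(makeTrace("HR", 0:10, rep(80, 11)))))
  alarms <- mkAlarm("p1", "SVT+BP", 500)
  truth <- mkTruth("p1", "svt_bp", 400, 700)
  s2 <- summarizeCohort(metricsFromCounts("SVT+BP", 1, 0),
                        alarms = alarms, truth = truth, records = recs)
  expect_equal(s2$patient_days, 2)
  expect_equal(s2$table$tn_time_int, 1)
})
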