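# icualarms

Cross-sensor alarm rules for ICU vital-sign monitoring: a rule engine,
synthetic-cohort generator, and evaluation framework for multi-parameter
("smart") bedside alarms.

## The problem

Conventional bedside-monitor alarms watch one sensor at a time, and 80–99%
of what they produce is false — a damped arterial line reads as
hypotension, an infusion drives the CVP to 200 mmHg, a repositioned patient
shakes the ECG into "ventricular tachycardia". Caregivers learn to ignore
them (alarm fatigue). Clinicians, by contrast, cross-check sensors before
believing any of them: a real tachycardia shows up on the ECG, the pulse
oximeter *and* the arterial line; a real shock state depresses arterial
pressure *and* perfusion while venous and pulmonary pressures move in the
pattern of its mechanism.

`icualarms` implements that logic as a testable rule engine. An alarm
scenario is a conjunction of up to four single-parameter triggers; the
alarm fires only when every condition holds within a co-occurrence window,
so single-sensor artifacts are suppressed by construction. The package is
aimed at researchers studying alarm algorithms and false-alarm suppression
who need a reference implementation plus ground-truthed synthetic data to
evaluate it against.

## The model

A **trigger** on channel *x(t)* is one of:

* *absolute sustained*: `x(t') > θ` (or `<`, strictly) for all
  `t' ∈ [t − d, t]` — "Pulse > 110 bpm for 20 s";
* *relative change*: the 10-s median-smoothed value `s(t)` satisfies
  `s(t) ≥ (1 + δ/100) · s(t − ℓ)` (rise; analogously fall, or an absolute
  delta such as "+30 bpm") for some lag `ℓ ∈ (0, W]` — "+40% within 59 s";
* *flag present*: a 0/1 rhythm annotation held for `d` seconds.

A **scenario rule** combines 1–4 triggers as a conjunction: it fires at the
earliest `t` at which every trigger slot has an active interval overlapping
`[t − C, t]` (co-occurrence window `C`, default 60 s), then stays silent
for a refractory period (default 300 s). Missing data never counts as
evidence. Five scenarios are built in: **SVT+BP**, **Vtach+BP**,
**LV shock**, **Tamponade**, **Hypovolemia** (see `?builtinScenarios` for
every limit).

Evaluation classifies each alarm-side event as TPRE / TP Predict /
FP Artifact / FP Insufficient-Definition and each miss as FN (threat,
non-threat, or sensor-off), then computes per-scenario positive predictive
value

```
PPV = TP / (TP + FP_artifact + FP_insufficient_definition)
```

## Worked example

Simulate two patients for four hours with two engineered SVT episodes, one
cardiogenic-shock episode and one alarm-provoking CVP infusion artifact,
run the five built-in rules in compatibility mode (no plausibility
screening, as in monitors that cannot read a parameter twice), and
evaluate:

```r
library(icualarms)

spec <- cohortSpec(nPatients = 2, duration = 14400,
  plan = data.frame(kind = c("svt_bp", "lv_shock", "artifact_cvp_spike"),
                    count = c(2, 1, 1), margin = 0.1),
  seed = 42)
sim <- simulateCohort(spec)
det <- detectAlarms(sim$records, compatibilityMode = TRUE)
cls <- classifyEvents(matchAlarms(det$alarms, sim$truth))
rows <- do.call(rbind, lapply(vapply(builtinScenarios(), ruleName, ""),
                              function(s) computeMetrics(cls, s)))
summ <- summarizeCohort(rows, alarms = det$alarms, truth = sim$truth,
                        records = sim$records)
print(summ$table, row.names = FALSE)
cat(sprintf("overall FP fraction: %.3f over %d patient-days\n",
            summ$overall_fp_fraction, summ$patient_days))
```

```
    scenario n_events tp fp_art fp_ins_def ppv fn tn_time_int
      SVT+BP        2  2      0          0   1  0           0
    Vtach+BP        0  0      0          0  NA  0           2
    LV shock        1  1      0          0   1  0           1
   Tamponade        1  0      1          0   0  0           1
 Hypovolemia        0  0      0          0  NA  0           2
overall FP fraction: 0.250 over 2 patient-days
```

Each engineered episode produced exactly one true-positive alarm of its own
scenario. The infusion artifact — a 200 mmHg CVP reading amid the
transducer disturbances that accompany it — fooled the tamponade rule
(`FP_ART`). Re-running with
`detectAlarms(sim$records, plausibility = list(CVPmean = c(-5, 40)))`
screens the impossible CVP value and removes that false positive; the
screen is exactly what compatibility mode forbids.

A thin command-line wrapper is installed at
`system.file("scripts", "icualarms.R", package = "icualarms")`.

## Scope

Numerics-level processing only (≈1 Hz monitor exports): no waveform
analysis, no arrhythmia detection from raw ECG, and no bedside
integration. The synthetic generator is a stand-in for clinical data — see
the methods vignette (`vignettes/alarm-correlation.Rmd`) for what it does
and does not emulate.
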