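---
title: "Correlating sensors to raise alarm positive predictive value: methods"
author: "icualarms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlating sensors to raise alarm positive predictive value: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the trigger and
conjunction semantics, the parameters that matter and why their defaults
are what they are, what the synthetic generator emulates (and does not),
and the design decisions taken where the underlying alarm-surveillance
practice leaves the behaviour open.

## 1. The monitoring model

The engine works on monitor *numerics* — the once-per-second derived values
(heart rate, systolic arterial pressure, mean CVP, perfusion index, ...)
that bedside monitors export — never on raw waveforms. Every record is a
set of per-channel time series (`VitalTrace`) with strictly increasing
timestamps in seconds from record start; `NA` marks missing data.

Three assumptions shape everything downstream:

* **Canonical 1 Hz grid.** All trigger evaluation happens on a uniform
  1 sample/s grid. Monitors export numerics near this rate; the exact rate
  of any given device is not standardized, so the grid rate is a parameter
  (`rate`) of every evaluator, with 1 Hz the default.
* **Staleness is worse than absence.** Resampling carries the last
  observation forward at most `gapTolerance = 10` s; beyond that the grid
  point is missing. A stale pressure held for minutes would fabricate
  exactly the kind of sustained-violation evidence the engine is supposed
  to demand; ten seconds covers ordinary numerics jitter without doing so.
* **Missing data is never evidence.** A gap breaks the continuity of an
  absolute trigger and removes both the baseline and the current value of
  a relative trigger. A disconnected sensor therefore silences the rules
  that need it — which is the correct behaviour, and is what the
  `FN_SENS_OFF` classification later accounts for.

## 2. Trigger semantics

**Absolute sustained** (`"lower & upper violation for x seconds"`): the
value must be *strictly* beyond the threshold — a rule printed "> 110 bpm"
fires at 110.01 and not at 110.0 — continuously for the stated duration.
On the grid this means a violation run whose span reaches `duration`; the
active interval starts once the evidence is complete (`run start +
duration`) and ends when violation ceases.

**Relative change** (`"relative triggers in % over a defined time"`): the
current *smoothed* value is compared with the smoothed value some lag back,
for every lag up to the window length; the change test is inclusive ("at
least" the stated percent or delta). Smoothing is the trailing 10-s median:
a single-sample spike then neither triggers a change nor corrupts the
baseline it is judged against. Ten seconds is the smallest window that
reliably absorbs one- or two-sample telemetry glitches while keeping the
detector responsive within the shortest published window (20 s); raw-sample
comparison amounts to `smoothing = 0` and is available for sensitivity
analysis.

One published rule reads "−20% within 120 sec / 10 min". We interpret it
as: the fall must complete within 120 s, but the trigger remains *active*
for the balance of ten minutes (`scope = 600`), long enough to co-occur
with companion conditions that need 300 s of evidence. Both windows are
explicit `TriggerSpec` fields, because the original semantics are not
recoverable: a reader who prefers a different reading can set them.

**Flag present**: 0/1 rhythm annotations (the monitor's ventricular
tachycardia call) are carried as a channel, with a 5-s persistence
requirement standing in for the monitor's internal arrhythmia detector,
which is out of scope. The PVC channel is carried in the Vtach+BP rule's
required-sensor set but bears no numeric limit of its own, mirroring the
published parameter table, which pairs it with the rhythm annotation
rather than a count threshold.

### Numerical notes

The evaluators are exact, not approximate. A relative trigger "rise ≥ p%
at some lag ≤ W" is equivalent to comparing the current smoothed value
against the windowed *minimum* of the smoothed series (maximum, for
falls), because the comparison is monotone in the baseline; percent
thresholds are confined to (0, 100] to keep the scale factor positive, and
non-positive baselines (possible after clipping, or on pressure channels)
are masked out of the reference rather than collapsing the window — a
percent change from a non-positive baseline is undefined. Windowed
extremes use an O(n) block prefix/suffix scan and the trailing median
re-aligns the C-level running median, with direct recomputation wherever a
window touches missing data. The test suite holds both evaluators to
*exact* agreement with brute-force per-sample scans on a thousand random
traces; degenerate inputs (window not shorter than the record, empty
traces, all-missing windows) return empty results, with a warning where
the configuration is suspect.

## 3. Conjunction, eligibility, refractory

A scenario rule is an AND over its trigger slots: the alarm fires at the
earliest instant at which every slot has an active interval overlapping
the trailing co-occurrence window `C`. The published rule table lists up
to four conditions per scenario but never states the combinator; AND is
the only reading consistent with the stated purpose — cross-sensor
*confirmation* — and `C = 60` s acknowledges that the confirming sensors
respond on different time scales (a perfusion-index fall completes in
seconds; a 300-s pressure criterion matures minutes later). `C` is a rule
field, not a constant.

Two refinements:

* **Either/or slots.** The hypovolemia definition may take its blood
  pressure from the arterial line or the cuff; those two triggers share
  one slot, satisfied by either, and eligibility requires only one of the
  two sensors. Declared per rule via `eitherGroups`.
* **Fallback channels.** "HR (Pulse)" notation: when the primary channel
  is absent from a record, the declared fallback trace is evaluated
  instead. The fallback engages per record, not per gap — a patient
  monitored without ECG uses the oximeter rate throughout, but a
  transient ECG dropout does not silently switch sensors mid-episode.

A record lacking a rule's required sensors (more than half missing counts
as absent) is *ineligible*: the rule emits no alarms there and the record
contributes no events to that rule's evaluation, mirroring the study
practice of not analyzing events whose requisite sensors were off the
patient.

After firing, a rule is silent for `refractory = 300` s, and no two alarms
from one rule are ever closer than that, even when the condition clears
and recurs sooner. A persistent condition re-alarms every refractory
period — an deliberate choice over one-alarm-per-condition-episode, since
a shock state that persists for half an hour should not be representable
by a single line in a log reviewed once daily.

## 4. Compatibility mode and the plausibility screen

The study software could not consult the same parameter twice within one
definition, which made it impossible to *screen* a parameter (e.g.
"CVP > 16 required, but ignore CVP readings outside −5..40 mmHg") — and
extreme-value artifacts on the CVP were reported as the dominant false
positives of the venous-pressure scenarios. The engine reproduces both
worlds:

* `compatibilityMode = TRUE`: one look per parameter; any configured
  plausibility limits are ignored.
* Default mode: `plausibility = list(CVPmean = c(-5, 40), ...)` blanks
  implausible readings to missing *before* trigger evaluation, so an
  artifactual 200 mmHg spike cannot sustain a venous-pressure criterion.

The carrier ranges of the data model (e.g. pressures in [−50, 400] mmHg)
are deliberately wider than plausibility: the record must be able to
*carry* a 200 mmHg CVP or a −10 mmHg arterial reading, because observing
the engine's response to them is the point.

## 5. The synthetic cohort generator

No clinical data accompany this package, so the generator is the study
population stand-in: records are judged against *engineered* ground truth
rather than clinician adjudication.

**Baseline physiology** is stationary lag-1 autoregressive wander around
stable means (HR 80 ± 4 bpm, ARTsys 120 ± 6, ARTmean 85 ± 5, CVP 8 ± 2,
PAPdia 12 ± 2, Perf 2.0 ± 0.3, NIBPm 85 ± 5 mmHg; φ = 0.95 at 1 Hz). The
autocorrelation gives minute-scale physiological drift rather than white
noise; the means and spreads describe a haemodynamically stable
postoperative cardiac-surgery patient sitting far from every alarm limit,
which is what makes the false-alarm floor of the noise model empirically
zero (a property the tests check over ten patient-days). The oximeter
`Pulse` is the ECG `HR` plus small independent sensor noise, so rate
sensors agree except during engineered motion artifacts.

**Episodes** are deterministic ramp–hold–recover trajectories whose
plateau is derived arithmetically from the scenario's own limits and one
scalar severity margin *m*: every threshold is exceeded (m > 0) or
undershot (m < 0) by |m|, multiplicatively for thresholds and percent
changes, additively scaled for "+30 bpm"-style deltas. The plateau is
noise-free and the ramp completes within half the shortest relative
window, so whether each trigger fires is provable by arithmetic — ground
truth is analytic, not empirical. Baselines for percent targets are the
10-s pre-onset median, the same reference the smoothed relative trigger
sees, which keeps ±10% margins decisive in the presence of baseline
wander. Sub-threshold episodes are guaranteed silent by their *absolute*
triggers (a flat plateau strictly on the wrong side of the threshold);
their relative triggers may flicker against noisy baselines, but the
conjunction cannot complete.

One physiological nesting is worth knowing: a ventricular-tachycardia
episode severe enough to satisfy Vtach+BP (rate +30 bpm, pulse >110,
pressure −30%) also satisfies the SVT+BP definition — rapid rate with
hypotension is what SVT+BP detects. Both alarms firing on such an episode
is correct engine behaviour, as it would be on a real monitor running
both definitions; evaluation attributes each alarm to its own scenario's
truth only.

**Artifacts** reproduce the published failure modes: CVP infusion spikes
(200 mmHg), damped arterial waveforms (systolic collapses to ~70 mmHg
while cuff pressure stays normal), transducer leveling errors (constant
±20 mmHg offsets), motion (ECG-side rate spikes and rhythm-flag bursts
with the oximeter quiet), and sensor disconnects (missing stretches).
Singly, none of these can fire a multi-sensor rule — that suppression is
the central claim, and the tests assert it. The *alarm-provoking* CVP
artifact variant (requested by a positive margin in the cohort plan)
models the bedside reality behind the reported venous-pressure false
positives: infusion, flushing, and repositioning disturb several
transducers in the same minutes, so the CVP spike arrives together with
arterial damping, a pulmonary-pressure offset and a perfusion droop. The
extreme CVP value remains the linchpin — the plausibility screen removes
it and the conjunction then fails — which is exactly the screening
mechanism the engine exists to demonstrate. The generator schedules
planned items at least 600 s apart (so refractory periods and lookback
windows of consecutive episodes cannot interact) and artifacts are placed
like any other plan item; real artifact timing (clustering at nursing
shifts, infusion schedules) is not modelled.

**Determinism.** Each patient's seed derives from the master seed by a
counter-based scheme, so cohorts are bit-reproducible and patient *k*'s
record does not change when the cohort grows.

What passing tests on this generator shows — and what it does not: the
engine's trigger semantics, conjunction logic, artifact suppression and
classification arithmetic are verified against analytically known truth.
That is evidence about the *software*, not about clinical performance:
real vital signs have nonstationary baselines, correlated multi-channel
artifacts, treatment responses, and adjudication ambiguity that no AR(1)
model emulates. Published field counts (hundreds of events over hundreds
of patient-days) depend on clinical data this package does not have and
are reproduced only at the arithmetic level: feeding the published
per-scenario counts through `metricsFromCounts()` and
`summarizeCohort()` recovers the published PPVs (0.807, 1.0, 0.81, 0.04,
0.27) and the 29% overall false-positive fraction. The narrative counts
for the SVT scenario (171 true positives among 212 classified alarms,
PPV 0.807) and its printed table row (170 + 17 + 22 = 209 ≠ the stated
221 events) disagree slightly in the source; the package reproduces the
narrative arithmetic for the PPV and the printed per-scenario totals for
the overall fraction, and documents the discrepancy rather than resolving
it.

## 6. Evaluation taxonomy

Alarms are matched to truth intervals (tolerance 60 s — one monitor
trend-screen unit; the daily-review adjudication the taxonomy comes from
had no finer granularity), greedily, earliest first, one-to-many: a truth
event absorbs all its refractory-separated repeats and counts once
(`alarmCounting = "alarms"` counts each repeat). Clinical truth absorbs
only its own scenario's alarms; artifact truth absorbs any scenario —
an artifact does not care which definition it fooled. Classification then
assigns exactly one label per event: `TPRE` / `TP_PREDICT` on the alarm
side of clinical truth (predictive when every matched alarm precedes
onset), `FP_ART` for artifact-matched alarms, `FP_INS_DEF` for alarms
co-occurring with an explicit `confounder` truth label (an assist-device
patient whose physiology legitimately satisfies a definition — context
the engine cannot infer, so it must be declared), and `FN_TH` /
`FN_NO_TH` / `FN_SENS_OFF` for misses. An alarm with no ground-truth
correlate at all is classed `FP_ART` with its rationale noted: the
taxonomy has no residual false-positive category, and in synthetic
cohorts such alarms are artifact- or noise-triggered by construction.
Quiet (patient-day, scenario) pairs are counted as `TN_TIME_INT`.

Two conservation properties are enforced by tests: every alarm lands in
exactly one alarm-side event; and per scenario, alarm-side events =
TP + FP_art + FP_ins_def, which is the PPV denominator.

## 7. Problem sizes and test design

The suite verifies trigger evaluators against brute-force oracles on
1,000 random traces of up to 600 samples; detectability on a 10-patient ×
24-h cohort carrying 20 detectable (+10%) and 20 sub-threshold (−10%)
episodes of each scenario (sensitivity 1.0, zero sub-threshold alarms);
exact PPV recovery (20 true episodes + 5 alarm-provoking artifacts →
PPV = 0.80, rising to 1.0 with the CVP screen) on a 10-patient × 8-h
cohort; and the false-alarm floor on ten quiet patient-days. These sizes
were chosen so that every property is exercised at the scale of the
original monitored unit (ten beds, day-long records) while each margin
remains decisive by arithmetic rather than by luck.

## 8. Known limitations

* Numerics only; no waveform analysis, no arrhythmia detection, no ST
  segments. The rhythm flag abstracts the monitor's detector.
* The AND combinator, co-occurrence window, refractory policy and
  relative-trigger reference are principled reconstructions of
  underspecified monitor behaviour, exposed as configuration rather than
  hidden as constants.
* The generator's artifacts are independent plan items; real artifact
  bursts are temporally clustered and cross-correlated beyond the one
  compound (alarm-provoking CVP) case modelled here.
* Sensitivity/specificity against real adjudicated clinical data are out
  of scope: no such data ship with the package, and nothing here should
  be read as a clinical performance claim.
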