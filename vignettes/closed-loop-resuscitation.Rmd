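---
title: "Methods: the closed-loop resuscitation controller and its in-silico test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the closed-loop resuscitation controller and its in-silico test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`refitsim` couples a resuscitation decision engine to a lumped-parameter
porcine hemorrhage model so the whole protocol — diagnosis, proportional
fluid dosing, vasopressor titration, stopping rules, failsafe — can be
exercised deterministically. This vignette records the models, the
parameters that matter, the calibration anchors, and the design decisions
taken where the protocol description left the design open.

## The controller

The decision engine is a finite-state machine ticked at 1 s with modes
IDLE, INITIAL_BLOOD, CACL2, SECOND_BLOOD, CYCLING, FAILSAFE and STOPPED.
Within CYCLING the 15-min cycle has three 5-min phases: treatments are
issued in the first five minutes, the second five are equilibration, and
the last five reassess the state that governs the next cycle's treatment.
The snapshot governing a TREAT decision is the last valid snapshot of the
preceding ASSESS phase.

Thresholds and doses (all operator-configurable via
`controller_config()`):

* **Need for resuscitation**: MAP < 60 mmHg *or* HR > 110 min⁻¹. The
  start/stop wording pairs the two thresholds with "their absence" as the
  stopping rule; we read initiation as the disjunction and stopping as the
  conjunction of both vitals being within limits, since a conjunctive
  trigger would ignore profound hypotension with a normal heart rate.
  Whether normotensive tachycardia alone should trigger fluid, pressors or
  neither is genuinely open; under the disjunction it can trigger fluid
  when PPV indicates preload dependence, which is the conservative reading.
* **Crystalloid**: none below PPV 10 %, 5 / 8 / 10 ml/kg on the left-closed
  bands [10, 30), [30, 50), [50, ∞) %. Comparisons are exactly as printed:
  `>=` at the band edges, strict `<`/`>` at the MAP/HR thresholds.
* **Norepinephrine**: start 0.03 µg/kg/min (only after the first
  crystalloid bolus has been commanded, and never within the same TREAT
  phase), ±0.01 steps, cap 0.3. The up-step granularity is printed; the
  wean magnitude is not, so weaning uses the same 0.01 step, one step per
  qualifying cycle (MAP held above target for the whole cycle, no fluid
  that cycle, Ea_dyn > 1).
* **Failsafe**: any tick with an invalid snapshot freezes the machine —
  the norepinephrine rate is held and no new boluses start (boluses
  already infusing run to completion; commands are executed at issue, so
  there are no queued-but-unstarted boluses to cancel). After the signal
  returns, one full 15-min observation interval elapses before cycles
  resume; the observation stands in for the preceding cycle in the weaning
  gate, so a pressure overshoot accumulated during the outage is weaned
  immediately afterwards.
* **Second blood unit**: evaluated once, after the CaCl₂ infusion plus one
  equilibration phase; if the stopping rules are met at that check the
  second unit is skipped permanently. Re-attempting blood in later cycles
  on deterioration is left out deliberately: the protocol narrative treats
  the two units as the initial field sequence.

Time to initial stabilization follows the ledger definition: minutes from
activation to the start of the first 15-min cycle, after the first
crystalloid bolus, in which no treatment was given or changed. Subjects
whose two blood units alone satisfy the stopping rules never receive
crystalloid, leaving that definition undefined; run results therefore also
carry a boolean `stabilized` that additionally accepts "no crystalloid ever
needed and at least one command-free cycle".

## The simulator

The porcine model is quasi-static in its hemodynamics and dynamic in its
balances, integrated by explicit Euler at dt = 0.1 s (stiff dynamics are
absent; determinism and transparency are worth more here than higher-order
integration). States: blood volume, hemoglobin, lactate, and derived
circulation.

With $v = V/V_0$ (blood volume normalized to baseline, $V_0$ = 70 ml/kg):

* **Cardiac output**: $CO = V_{max}\,(1 - e^{-k s})$ on stressed volume
  $s = (v - v_u)/(1 - v_u)$, $v_u = 0.30$; $k$ is set so the baseline
  volume reproduces the baseline CO exactly.
* **Vascular tone**: $SVR = SVR_0\,(1 + g_b \max(0, MAP_{set} - MAP))
  \,(1 + E_{max}\,r/(EC_{50} + r))\,(1 - \phi)\, f_{dist}$ — a
  piecewise-linear baroreflex ($g_b$ = 0.01 /mmHg), an Emax norepinephrine
  effect ($E_{max}$ = 1, $EC_{50}$ = 0.1 µg/kg/min), a lactate-coupled
  vasoplegia term $\phi = \min(0.12\,(lactate - 1), 0.4)$, and an
  exogenous disturbance factor for transfer dips. Because SVR is linear in
  MAP below the setpoint, $MAP = CO \times SVR$ has a closed-form fixed
  point, which we use instead of an iterative pass.
* **Heart rate**: $HR = HR_0 + 1.0 \times \max(0, MAP_{set} - MAP)$,
  giving the observed tachycardia of decompensation.
* **Bleeding**: $q = q_0\, e^{-\lambda t}\,(MAP/MAP_0)^{0.8}\,
  [\gamma\ \text{if packed}]$ with $q_0$ = 78 ml/min (30.8 kg), $\lambda$
  = 0.028 min⁻¹, packing factor $\gamma$ = 0.10.
* **Transcapillary refill**: $\min(10\ \text{ml/min} \times
  \text{deficit fraction},\ \text{reserve})$, reserve 1000 ml. Without
  refill the quasi-static closure cannot reproduce the partial MAP
  recovery between the hypotension trigger and the start of resuscitation,
  nor the hemoglobin dilution across the bleed; both emerge from it.
* **Oxygen transport**: $DO_2 = 1.34 \cdot Hgb \cdot CO \cdot 10 \cdot
  SaO_2$; consumption is demand-limited by a maximal extraction ratio of
  0.60, so SvO₂ floors near 40 % in deep shock; the oxygen deficit drives
  lactate production against first-order clearance (0.02 min⁻¹).
* **Death**: MAP below 20 mmHg continuously for 5 min; absorbing.
* **PPV**: a decreasing logistic in $v$ (floor 2 %, range 60, midpoint
  0.78, scale 0.06), below 10 % at baseline and far above 30 % at
  pre-resuscitation hypovolemia. Ea_dyn scales with total vasomotor tone
  relative to baseline (0.85 at rest), and SVV = PPV/Ea_dyn.

The waveform generator emits one beat per cardiac interval with pulse
pressure proportional to stroke volume (28 mmHg at baseline) and a
sin⁵ pulse shape whose time-mean matches the clinical MAP estimate
(diastolic + PP/3). The respiratory modulation (ventilator at 15 /min)
rides on the systolic peak over a common diastolic level, keeping the
waveform continuous at the troughs so trough-to-trough beat detection
recovers pulse pressures exactly; PPV and SVV modulation depths equal the
model's true values, and round-trips through the feature extractor recover
them within a fraction of a percentage point.

## Calibration

All functional forms above are the package's own: the study this emulates
reports animal measurements, not models. Every free parameter was fitted
once to the printed anchors and then frozen:

* baseline row — MAP 68.8, HR 82.2, CO 2.75 l/min, SvO₂ 57 %, Hgb 10.6
  g/dl: built into the constructors as an exact fixed point;
* the untreated natural history — the MAP < 40 trigger reached in ~26 min
  (< 30 min), one-hour mortality ≈ 50 % in a default cohort of 200
  (48.6 % mean across six seeds at the frozen values, ±3 % seed-to-seed),
  deaths concentrated at 40–55 min, and survivors persisting in
  compensated shock around MAP 45–50 at 3 h;
* the treated arc — pre-resuscitation hemodynamics in deep shock
  (MAP ≈ 44, CO ≈ 1.4, HR ≈ 106, Hgb ≈ 9, SvO₂ ≈ 40), both blood units
  required, crystalloid and low-dose norepinephrine engaged, stabilization
  at ~45–50 min after activation, MAP overshooting into the high 60s at
  stabilization.

Cohorts jitter weight (30.8 ± 0.7 kg) and baseline MAP (± 3.7), Hgb
(± 1.2) and SvO₂ (± 6) at their printed dispersions; invented parameters
(bleeding kinetics, Starling ceiling, refill, vasopressor sensitivity,
responsiveness midpoint) carry a 10 % coefficient of variation. Baseline
HR is jittered at 10 % truncated to [55, 105] min⁻¹ rather than its printed
±17.6, because a baseline above the 110 min⁻¹ threshold would make the
stopping rules unsatisfiable by construction. The printed CO dispersion
(±1.31, ~48 %) is treated as measurement scatter, not biological
variation.

## What the generator does and does not emulate

It emulates: pressure- and time-dependent uncontrolled bleeding with
packing, preload-dependent output, reflex tachycardia and
vasoconstriction, vasoplegia requiring pressor support, crystalloid
redistribution (25 % intravascular retention), hemodilution, supply-
dependent oxygen consumption, and ventilator-synchronous PPV/SVV.

It does not emulate: real-device measurement noise or motion artifact,
arrhythmia, coagulopathy or temperature, anesthetic pharmacology, acid–
base beyond lactate, or spontaneous breathing (PPV/SVV are meaningful only
under controlled ventilation — as in the protocol). CaCl₂ is commanded and
logged but has no modeled hemodynamic effect, since no quantitative
physiology is attributed to it. Passing tests therefore demonstrate
protocol logic and closed-loop behavior under clean signals, not
robustness to clinical artifact — artifact rejection is explicitly out of
scope of the feature extractor.

## Numerical and interface choices

* Control tick 1 s; pig integration at dt = 0.1 s (ten substeps per tick);
  all phase boundaries aligned to the tick.
* One windowing engine: the 20-s feature window drives PPV, SVV, MAP and
  HR; the 5-min window belongs only to the hypotension trigger
  (> 80 % of samples strictly below 40 mmHg, window fully covered).
  Whether the source monitor averaged SVV over 20 s or longer is unknown;
  a single window keeps Ea_dyn internally consistent.
* SVV is defined symmetrically to the printed PPV formula
  (100·(SVmax−SVmin)/SVmean over the same window), making Ea_dyn = PPV/SVV
  well defined and testable.
* Snapshot HR uses the inter-beat intervals spanned by the window,
  60·(n−1)/(t_n − t_1) — exact for regular rhythms, free of the ±3 bpm
  quantization a bare beat count over a 20-s window would carry.
* Beat detection: trough-to-trough segmentation with a 0.25-s refractory
  period and a 5-mmHg minimum pulse pressure; a flat record yields zero
  beats (feeding the validity logic) rather than an error. Validity
  horizon: 5 s without a beat, long enough to ride over a skipped beat,
  short enough to catch a disconnect within one tick cadence.
* Degenerate inputs: empty MAP series raise an error (unusable input);
  fewer than five beats in the window make PPV/SVV undefined and the
  snapshot invalid; negative PPV or infusion rates are rejected.
* Deterministic throughout: the only RNG sits in cohort sampling, seeded
  explicitly; identical configuration yields byte-identical trend and
  ledger files.

## Problem sizes used by the test suite

Unit and property tests run on constructed beat tables and scripted
snapshot streams in milliseconds. The end-to-end checks use full-length
closed-loop runs (~260 simulated minutes, ≈10 s wall-clock each), a
treated cohort of 12 (≈2 min) and an untreated cohort of 200 followed for
60 simulated minutes through the vectorized stepper (≈1 min). Shorter
45–60-min resuscitation windows are used where only the pipeline ordering
or determinism is under test.

## Known limitations

The untreated mortality calibration sits on the knife-edge the statistic
itself implies — a cohort whose median animal hovers near the death
threshold at one hour — so the fraction is sensitive to the bleeding
parameters (a 5 % change in initial bleeding rate moves it by ~10
percentage points). Times to stabilization and dose totals are emergent
properties of an invented physiology; they land in the reported ranges but
are not reproductions of animal data and are not asserted numerically
anywhere. The simulated monitoring chain is idealized: feature recovery
errors are fractions of a point, whereas real devices disagree with each
other by more.
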