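# refitsim

Closed-loop resuscitation of severe uncontrolled hemorrhagic shock, as a
fully testable in-silico system.

Severe traumatic hemorrhage usually happens far from definitive care, and
first responders can rarely do more than control external bleeding and give
fluid or blood. A physiologically based closed-loop controller (PCLC) that
reads an arterial pressure line, diagnoses circulatory insufficiency, and
drives infusion pumps autonomously can temporize such patients for hours of
ground or air transport. `refitsim` implements one such controller — the
ReFit algorithm, built on functional hemodynamic monitoring — together with
a calibrated lumped-parameter porcine model of liver-laceration hemorrhage,
so that the controller's diagnosis, proportional dosing, vasopressor
titration, stopping rules and failsafe behavior can all be exercised and
verified at desk scale.

## The algorithm

The controller reads windowed features of the arterial signal over a 20-s
moving window:

- **MAP**, **HR** — mean arterial pressure and heart rate;
- **PPV** = 100·(PPmax − PPmin)/PPmean, the respiratory variation of the
  beat pulse pressure (volume responsiveness under controlled ventilation);
- **SVV** — the same statistic on beat-to-beat stroke volume;
- **Ea_dyn** = PPV/SVV, dynamic arterial elastance, a surrogate of
  vasomotor tone.

Resuscitation is needed while MAP < 60 mmHg **or** HR > 110 min⁻¹; it stops
when both are within limits. On activation the controller infuses 250 ml
whole blood over 5 min, then 1 g CaCl₂ over 5 min, and a second blood unit
only if the stopping rules are still unmet. It then runs 15-min cycles in
three 5-min phases (treat / equilibrate / reassess):

| PPV at assessment | lactated Ringer's bolus |
|---|---|
| < 10 % | none |
| 10 – <30 % | 5 ml/kg |
| 30 – <50 % | 8 ml/kg |
| ≥ 50 % | 10 ml/kg |

Norepinephrine starts at 0.03 µg·kg⁻¹·min⁻¹ (only after the first
crystalloid bolus), moves in 0.01 steps up to 0.3, and is weaned one step
per cycle only when MAP held above target for the whole cycle, no fluid was
needed, and Ea_dyn > 1. If no physiologic input is sensed, the controller
falls to a fixed mode: norepinephrine held, no new boluses; after the
signal returns it observes for 15 min before resuming cycles.

The simulator closes the loop: Frank–Starling cardiac output, baroreflex,
norepinephrine Emax effect, lactate-coupled vasoplegia, pressure- and
time-dependent bleeding with packing, transcapillary refill, oxygen
transport and lactate kinetics, plus a beat-level arterial waveform
generator whose respiratory modulation realizes the PPV/SVV constructs.

## Worked example

```r
library(refitsim)

run <- run_scenario(scenario_lab(seed = 1))
(run$times$trigger - run$times$injury) / 60   # 25.8 min to MAP<40 trigger
run$time_to_stabilization_min                 # 50 min
run$survived_3h                               # TRUE
run$ledger
#>   t_issued        channel     kind amount      unit duration_min
#> 1     5148    whole_blood    bolus 250.00        ml            5
#> 2     5448          cacl2    bolus   1.00         g            5
#> 3     6048    whole_blood    bolus 250.00        ml            5
#> 4     6348        ringers    bolus 246.40        ml            5
#> 5     7248        ringers    bolus 154.00        ml            5
#> 6     7248 norepinephrine rate_set   0.03 ug/kg/min           NA
#> 7    12648 norepinephrine rate_set   0.02 ug/kg/min           NA
```

The default animal bleeds to the hypotension trigger (MAP < 40 mmHg over
>80 % of a 5-min window) 25.8 min after the laceration; the liver is packed,
and 30 min later the controller activates. It gives the two blood units
(MAP is still below target at the check), an 8 ml/kg then a 5 ml/kg
Ringer's bolus as PPV indicates shrinking but present volume
responsiveness, starts norepinephrine at 0.03 µg/kg/min when hypotension
persists after the first crystalloid, and later weans one step once MAP has
held above target with Ea_dyn > 1. Initial stabilization — the first quiet
15-min cycle after the first crystalloid — comes 50 min after activation.
`render_trends(run)` draws the standard stacked trend panels
(norepinephrine, boluses, MAP, SvO₂, HR, lactate).

Cohorts ride on the same machinery:

```r
run_cohort(scenario_natural(seed = 1, follow_untreated_min = 60), n = 200)$summary
run_cohort(scenario_lab(seed = 1), n = 12)$summary
```

A thin command-line front-end is installed with the package
(`inst/scripts/refit`): `refit run --scenario transport --seed 3 --out out/`.

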