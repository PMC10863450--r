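# emaflow

A headless R engine for designing and stress-testing mobile e-coaching
studies — ecological momentary assessment (EMA), ecological momentary
interventions (EMI) and just-in-time adaptive interventions (JITAI) —
entirely at the desk, from declarative study documents, event logs and
seeds.

Digital intervention platforms deliver psychological programmes as a
hierarchy (study → interventions → modules → items) in which module
availability is computed per participant by timing rules, and participants
are steered by push notifications. Getting that rule logic right *before*
a cohort is enrolled is hard: timing rules interact, notifications have
strict semantics, and derived feedback depends on cohort-level aggregates.
`emaflow` implements that behavioral core so researchers and intervention
designers can validate study definitions, trace per-participant module
lifecycles, plan notifications, evaluate calculated variables, aggregate
wearable biomarker streams and simulate virtual cohorts with configurable
adherence — with no app, server or push infrastructure.

## What is implemented

* **Study definitions** — a canonical JSON schema (YAML accepted as an
  alternate surface) with a strict loader and a structural validator
  (`load_study()`, `save_study()`, `validate_study()`). Violations are
  data, not exceptions.
* **Module lifecycle state machine** — `LOCKED → OPEN → {COMPLETED,
  CLOSED}` per participant, driven by five opening rule kinds (relative to
  enrollment, relative to another module's completion, another module not
  finished by a deadline, an answer condition, a fixed date) and three
  closing rule kinds (answer condition, fixed date, relative to open).
  Rules combine as OR, earliest firing wins (`run_timeline()`, `step()`).
* **Notification planning** — opening notifications on fixed or uniform
  random intervals after open; reminders once a module has been available
  ≥ 15 min; closing notifications exactly 15 min before a predictable
  close; suppression for instances that already completed or closed
  (`plan_notifications()`).
* **Calculated variables** — a small expression language with `+ - * / ^`,
  parentheses, unary minus and the cohort aggregation functions
  `SUM_ANS`, `NUM_PS`, `NUM_P_ANS`, `MODE_ANS` (mean fallback when no
  unique mode exists) and `COUNT_ANS` (`parse_expr()`, `eval_expr()`).
* **Biomarker aggregation** — daily summaries of steps, pulse rate and
  sleep (episodes unioned as intervals, midnight-spanning sleep attributed
  to the waking day, wearable preferred over phone), plus a seeded
  synthetic stream generator (`aggregate_daily()`,
  `generate_biomarker_stream()`, `bind_as_variables()`).
* **Cohort simulation** — seeded virtual participants with configurable
  enrollment window, adherence probability, response latency and answer
  models; event logs replay through the scheduler to identical transitions;
  adherence reporting (`simulate_cohort()`, `adherence_report()`).

A thin command-line wrapper ships in `exec/emaflow`
(`validate`, `plan`, `eval`, `simulate`, `export`).

## Worked example

The packaged three-module self-reflection study (also shipped as
`inst/extdata/self_reflection.study.json`) has a welcome module open from
enrollment, a daily check-in opening a day after the welcome is completed
and closing 12 h later, and a support module that opens on low reported
mood or an unfinished check-in:

```r
library(emaflow)

s <- example_study()
print(s)
#> <study_definition> SELFREF1: "Self-reflection coaching example"
#>   1 intervention(s), 3 module(s), 6 item(s)

validate_study(s)          # zero rows: the definition is clean

sim <- simulate_cohort(s, simulation_config(
  n_participants = 20, horizon = 20160,       # two simulated weeks
  enrollment_window = 1440, adherence_prob = 0.7, seed = 42))
print(sim$report)
#> <adherence_report>
#>   overall completion rate: 0.660
#>   mean response latency:   91.8 min
#>   notifications planned:   opening 36, reminder 15, closing 8
#>   per module:
#>     m_checkin    opened  16  completed   8  rate 0.500
#>     m_support    opened  11  completed   7  rate 0.636
#>     m_welcome    opened  20  completed  16  rate 0.800
```

All 20 participants saw the welcome module; 16 completed it, so 16
check-ins opened a day later, of which half were completed before the
12-hour close. The support module opened for 11 participants (low mood or
a missed check-in). Cohort-level feedback comes from the expression
language over the simulated answer history:

```r
ctx <- eval_context(assigned = 20,
                    answers = answers_from_timelines(s, sim$timelines))
eval_expr("SUM_ANS(mood_today) / NUM_P_ANS(mood_today)", ctx)
#> [1] 6        # mean reported mood among the 8 participants who answered
eval_expr("NUM_P_ANS(mood_today)", ctx)
#> [1] 8
```

The notification plan is an ordinary data frame
(`dispatch_time, participant_id, module_id, kind, text`), e.g. the first
opening notification of the run dispatches at minute 213 for participant
`p008` the moment their welcome module opens.

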