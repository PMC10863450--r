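---
title: "The emaflow engine: scheduling rules, expressions and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The emaflow engine: scheduling rules, expressions and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emaflow)
```

## What the engine models

Mobile e-coaching platforms for ecological momentary assessment (EMA) and
just-in-time adaptive interventions (JITAI) deliver psychological programmes
as a hierarchy: a **study** holds one or more **interventions** (versions of
the programme), each intervention holds ordered **modules** (chapters), and
each module holds **items** — questions of various types or informative
content. Participants join a study with a short code and are either assigned
to an intervention or put on a waitlist. What makes such platforms
adaptive is that module availability is *computed* per participant from
timing rules, answers and derived quantities, and participants are steered
by push notifications.

`emaflow` re-implements that behavioral core as a headless, desk-scale
engine: everything is driven by declarative study documents, long-format
event logs, and seeds, so intervention logic can be designed, validated and
stress-tested without a mobile app, push infrastructure or real cohort.

## Module lifecycle semantics

Each module instance moves through `LOCKED → OPEN → {COMPLETED, CLOSED}`;
`COMPLETED` and `CLOSED` are terminal and there is no re-opening. Five
opening rule kinds are supported (a relative time after enrollment, a
relative time after another module's completion, a check that another
module was *not* finished by some offset after it opened, an answer
condition on an item, and a fixed date), and three closing rule kinds (an
answer condition, a fixed date, a relative time after the module opened).

The design choices that the rule list alone leaves open:

* **Rule combination is OR with earliest-wins**, for both opening and
  closing. A rule fires at the earliest minute its condition holds; among
  several rules the earliest firing one determines the transition time.
* **Completion** means every answerable item of the module has been
  answered at least once in the instance; `info_content` items require no
  interaction. An explicit completion event is also accepted (e.g. for
  info-only modules) but cannot bypass unanswered items.
* **Degenerate times clamp rather than error**: a fixed open time before
  enrollment opens at enrollment; a fixed close date before the open time
  closes the module the instant it opens (OPEN then CLOSED in the same
  minute, in that order).
* **"Not finished" checks need an open referent**: the check time is
  anchored at the referenced module's open time plus the offset; if the
  referenced module never opens, the rule never fires. Before the check
  time arrives the rule's outcome is deliberately *undetermined* — it
  cannot be known whether the participant will still finish in time.
* **Within one minute**, transitions already due from the pre-event state
  fire first, then the minute's events apply in kind order
  (`enroll < answer < module_completed < clock_tick`), then any transitions
  the events enabled (including cascades, e.g. a completion opening the
  next module with a zero offset). A consequence worth knowing: a close
  due at minute *t* beats an answer arriving at minute *t*.
* **Answers to non-open modules are rejected** without any state change;
  partial answers of a module that closes uncompleted are preserved in the
  export and flagged by the instance's final `CLOSED` state.

All clock quantities are integer minutes from a study-local epoch. The
finest granularity the notification semantics require is 15 minutes, so
minute resolution removes every sub-minute ambiguity while staying exact in
integer arithmetic. The engine is event-driven, but transition times are
the times at which rules actually *fire*, not the times of the events that
reveal them — the test suite holds `run_timeline()` to exact agreement with
a brute-force simulator that re-evaluates every rule every minute.

## Notifications

Three notification kinds attach to modules, and the validator enforces at
most one opening and one closing notification per module:

* **opening** — dispatched at a fixed interval after open, at a uniformly
  random integer minute inside a configured window after open, or at a
  fixed date (clamped to the open time);
* **reminder** — dispatched once the module has been available for at
  least 15 minutes; the default offset is that 15-minute floor and the
  validator rejects anything smaller;
* **closing** — dispatched exactly 15 minutes before the module closes,
  and therefore only allowed on modules whose closing rules make the close
  time predictable (a fixed date or a relative time after open). If a
  module stays open for less than the 15-minute lead, the notification is
  dropped and recorded as a planning violation rather than sent late.

No notification is dispatched for an instance that completed or closed
strictly before the dispatch time; completing *at* the dispatch minute
does not suppress. The planner is a pure function producing a dispatch
plan (a data frame), decoupled from any push transport, and every random
draw comes from a stream derived from `(seed, participant, module)` so
plans are reproducible and independent of iteration order. The paper's
behavioral contract — reminders at least 15 minutes after open, closing
notifications exactly 15 minutes before close — is asserted property-style
over 100 random cohorts in the test suite.

## The calculated-variables expression language

Calculated variables let a study designer derive quantities from answers at
runtime — for feedback text ("your 3-day average was 6") or timing rules
("skip the remaining questions when the participant feels well"). The
language has numeric literals, variable references, `+ - * / ^` with
standard precedence (`^` binds tightest and is right-associative, so
`2^3^2 = 512`), unary minus, parentheses, and five cohort aggregation
functions:

| Function | Meaning |
|---|---|
| `SUM_ANS(N)` | sum of all recorded responses to `N` |
| `NUM_PS(N)` | number of participants assigned to the intervention |
| `NUM_P_ANS(N)` | number of participants who answered `N` |
| `MODE_ANS(N)` | most frequent response; the mean of all responses when no unique mode exists |
| `COUNT_ANS(N, v)` | number of responses to `N` equal to `v` |

Decisions behind the corners the function list leaves open:

* `SUM_ANS` sums **all** recorded responses, not distinct values — the
  natural reading for cohort feedback, and the one that makes
  `SUM_ANS(N)/NUM_P_ANS(N)` a cohort mean when everyone answers once.
* "No mode" means the maximal frequency is shared by two or more distinct
  values; the fallback mean is taken over all answers (so `MODE_ANS` over
  `{1,2,3}` is 2).
* `COUNT_ANS` equality is exact on integers and within a 10⁻⁹ relative
  tolerance otherwise.
* Non-numeric answers are excluded from every aggregation (the exclusion
  count is tracked); aggregation over a variable bound to a text item is a
  validator error in the study document itself.
* A plain variable reference resolves to the scoped participant's most
  recent answer; aggregations always evaluate cohort-wide.
* **Undefinedness propagates**: a referenced variable with no answer, or
  `MODE_ANS` over zero answers, makes the whole expression undefined
  (`NA`), and a scheduling rule gated on an undefined expression simply
  does not fire. Operators evaluate left-to-right and short-circuit on an
  undefined operand. Division by zero with *defined* operands is an error,
  not `NaN` — silent `NaN`s in feedback text are worse than a loud failure.
* Aggregations over an unanswered (but defined) variable return the empty
  sum 0 for `SUM_ANS` and counts of 0 for `NUM_P_ANS`/`COUNT_ANS`.

The parser is a hand-written tokenizer plus recursive-descent parser with
fixed function arities checked at parse time; the evaluator is checked
against a naive fully-parenthesized recursive oracle on 1000 random
expressions over random contexts.

## Biomarker streams

Wearable/phone health data enters as long-format samples — daily step
counts, pulse-rate readings, pulse-rate variability values (ingested as
delivered; no RMSSD-style algorithmics), and sleep episodes as intervals —
and is aggregated to one summary per participant-day. Sleep episodes are
**unioned as intervals** before the duration is computed, so overlapping
reports are not double-counted, and an episode spanning midnight counts
towards the day on which it *ends*: `sleep_minutes` on day *d* reads as
last night's sleep. When a wearable and the phone both report sleep for a
day only the wearable episodes are used, because phone sleep is inferred
from alarms and non-usage while wearable sleep rests on heart-rate
measurement. Daily sleep is capped at 1440 minutes.

The synthetic generator stands in for the platform health-data
integrations. Its defaults describe a sedentary-to-moderately-active adult
cohort: daily step totals lognormal with median 7000 steps (`sdlog` 0.45),
split multinomially across the day's samples so daily sums follow the
configured lognormal exactly; pulse readings normal around 72 ± 8 bpm
clipped to the plausible (20, 260) band; sleep onset around 23:00 ± 30 min
with duration 450 ± 40 min; phone-derived episodes receive 60 min of extra
onset/duration noise. What it does *not* emulate: intra-day activity
structure beyond the sample split, weekday/weekend rhythms, missing-day
patterns correlated with adherence, and device-specific step-counting
bias — conclusions about those cannot be drawn from passing tests.
Summaries can be bound as the expression variables `steps_today`,
`mean_pulse_today` and `sleep_minutes_last_night`, so timing rules can
react to, say, a short night.

## The cohort simulator

`simulate_cohort()` drives the whole stack end to end. Participants enroll
uniformly over a configurable window and are assigned round-robin over the
study's auto-assign interventions (waitlist interventions receive nobody).
Whenever a module opens for a participant, one Bernoulli draw with
`adherence_prob` decides whether they engage; engaged participants answer
every answerable item after an exponential response latency (default mean
60 minutes, truncated implicitly: a response whose latency lands after the
module closed is simply never given — the prompt was missed). Answer values
come from per-item models, defaulting to uniform option codes for coded
items and uniform 1–10 for sliders and number inputs.

Every draw comes from a pseudo-random stream derived from
`(seed, participant_id)`, so cohorts are bit-reproducible and one
participant's trajectory does not depend on how many others are simulated.
The returned event log contains only effective events and replays through
`run_timeline()` to the identical transition list — the simulator is not a
second scheduler, it is a client of the real one. The adherence report
(completion rates, response latencies as completion-minus-open per
completed instance, notification counts) is a pure function of the logs;
with `adherence_prob = 0.7` and 200 participants on an always-open module
the observed completion rate falls within three binomial standard errors
of 0.7.

## Validation and serialization choices

One canonical JSON schema (`schema_version: 1`, fixed key order,
byte-stable output) with YAML accepted as an alternate surface syntax of
the same schema, so a single strict loader validates both. Unknown fields,
unknown item types and malformed rules are hard errors naming the
offending path — study documents are written by researchers, not
programmers, and silent tolerance hides typos. Semantic invariants
(reference resolution, notification cardinality and compatibility,
comparator legality on text items, aggregation over numeric variables,
and so on) are returned by `validate_study()` as a data frame of
violations rather than exceptions, stable-ordered by path; a study with
zero violations is guaranteed not to produce dangling-reference errors in
the scheduler or evaluator. The schema forbids sharing modules between
interventions — duplication keeps every rule reference local to one
intervention.

## Problem sizes and limitations

The property suites run at deliberately desk-scale sizes: 100 random
studies of up to 5 modules against the minute-by-minute oracle at horizons
of 2000–10000 minutes, 100 random cohorts for the notification invariants,
1000 random expressions against the naive evaluator, and a 200-participant
cohort for adherence recovery. These sizes make the full suite run in
about two minutes while leaving each property enough room to fail loudly.

Out of scope by design: re-opening or repeating modules, cross-study
dependencies, real wall-clock daemons and push delivery, behavior-change
effect modelling in the simulator (simulated answers have no treatment
response), sleep staging, and multi-study workspaces. The simulator's
adherence model is intentionally simple — one engagement probability and
one latency distribution — which is enough to exercise every scheduling
and notification path, but not to mimic the clustered, time-varying
non-adherence of real cohorts.
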