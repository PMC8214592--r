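---
title: "Methods: rule-based paracetamol dose surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based paracetamol dose surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosewatch)
library(dplyr)
```

## The surveillance problem

Adult paracetamol dosing is bounded by two limits: 4 g per 24 h
absolutely, and 60 mg per kg of body weight per 24 h relatively. Hospital
overdoses are rarely deliberate; they arise from process failures — an
intravenous course switched to oral without counting the doses already
given that day, an unscheduled night dose on top of a full 4 x 1 g
schedule, or two paracetamol-containing products co-prescribed.
`dosewatch` models the complete surveillance loop around this problem: a
prospective polling agent over the eMAR stream, a retrospective
calendar-day gold standard, a pharmacist triage layer, patient-level
detection-rate evaluation, and a synthetic cohort generator for
stress-testing the loop without hospital data.

Two deliberately different clocks are at the heart of the design. The
**engine** evaluates a trailing 24-h window `(t - 24 h, t]` at every new
administration; the **retrospective analysis** totals calendar days split
at local midnight. The windowed view reacts immediately but flags
"artificial" overdoses when a schedule drifts across midnight; the
calendar-day view is insensitive to drift but only available after the
fact. Both are kept, and the evaluation module quantifies their
disagreement as detection rates.

## Thresholds and boundary conventions

All limits live in one configuration object, `dose_thresholds()`:

| parameter | default | unit | meaning |
|---|---|---|---|
| `abs_daily_mg` | 4000 | mg | absolute overdose above this |
| `high_daily_mg` | 5000 | mg | upper edge of the 4–5 g band |
| `rel_daily_mg_per_kg` | 60 | mg/kg | relative overdose above this |
| `min_interval_h` | 4 | h | minimum dosing interval |
| `single_dose_mg` | 1000 | mg | trailing 4-h window limit |
| `weight_stale_days` | 14 | d | weight older than this is "old" |
| `forward_entry_max_min` | 60 | min | entry allowed before administration |
| `adult_age_min` | 18 | y | cohort inclusion, inclusive |
| `rel_validation_weight_kg` | 60 | kg | relative validation below this |
| `low_weight_kg` | 50 | kg | always recommend a reduction below this |
| `plaus_min_mg`, `plaus_max_mg` | 100, 2000 | mg | plausibility band per administration |

Every dose band is **strict on the lower side and half-open**: a day is
an overdose iff it exceeds 4000 mg, the 4–5 g band is `(4000, 5000]`, and
the high class is `> 5000`. Consequently a day of exactly 5 g falls in
the band, a day of exactly 6 g in the high class, and a 4 x 1 g schedule
(4000 mg) is a negative control. The 24-h window is half-open too:
a dose exactly 24 h old is excluded, the triggering dose included. The
short-interval alert is implemented as *trailing 4-h cumulative dose
above 1000 mg*, which reduces to "interval < 4 h" for standard 1 g doses
(a dose exactly 240 min after the previous one does not fire) and
generalizes to split doses. Weight records are stale strictly beyond 14
days: a 14-day-old weight is still used, a 15-day-old one raises the
old-weight alert and the mg/kg ratio is withheld — the legacy behavior
that blinds the agent to relative overdoses under stale documentation.

The plausibility band 100–2000 mg used by the cleaning step is a package
convention, not an observed rule: the smallest real product fraction is a
500 mg half tablet, and 2000 mg caps at twice the maximal single dose.
Records outside the band (think `1 mg`, `1000 g`, `1000 tablets`) are
repaired to the dose of the matching prescription order; with no matching
order they are excluded and counted rather than guessed.

Duplicates are defined by the key (patient, product, administration time,
dose amount, dose unit) — the minimal key that removes double data entry
without dropping legitimate repeat doses at different times.

## The polling engine

Ticks fall on fixed multiples of the poll interval (default 5 min) from
the start of the stream; a record is first seen at the first tick at or
after its entry time and is evaluated exactly once. Three policies govern
records whose documented administration time lies *after* the tick at
which they are first seen (the eMAR dialect allows charting up to 60 min
in advance):

* `skip_permanently` — the record never enters the cumulative sums. This
  reproduces the blind spot of the original production agent: a 5 x 1 g
  day with one forward-dated record never sums past 4000 mg, so the band
  alert is lost while a 6 x 1 g day still reaches 5000 mg and is caught.
* `defer_until_due` — evaluation waits until the administration time.
* `include` — all records count; this models a corrected engine and is
  the reference for the package's completeness property: any calendar day
  above 4 g is contained in the trailing 24-h window of that day's last
  dose, so the corrected engine alerts every such patient.

One modeling idealization is worth stating: window sums are computed over
the patient's full (policy-filtered) stream rather than only the records
entered before the evaluating tick. Entry latency therefore never changes
a window, results are deterministic and independent of the poll phase,
and the forward-dated blind spot is carried entirely — and explicitly —
by the `skip_permanently` flag. A production system would instead see a
transiently incomplete stream; for evaluation purposes that difference is
noise without a documented latency distribution to calibrate it.

The display layer is separate from detection: under `legacy_overshadow` a
short-interval alert suppresses same-tick band and mg/kg alerts from the
*displayed* set (never the over-5 g alert, never the raw log). Detection
rates in this package are computed on the raw log.

## Retrospective analysis and cause attribution

Calendar-day totals conserve milligrams by construction. Relative
findings use the weight measurement **closest in time in either
direction** to the day's administrations (represented by the midpoint of
the day's first and last dose) — deliberately different from the engine's
most-recent-prior rule, because the retrospective analyst can look ahead
while the agent cannot. Both rules coexist in the package and the
difference is one driver of the relative-detection gap.

Cause attribution is a deterministic cascade in observed-frequency order:
IV-to-oral switch (the day contains IV strictly before oral), then
out-of-schedule (an administration matching no order slot within ±60 min
and not covered by an on-demand order; slots of the neighbouring days are
included so the tolerance spans midnight), then duplicate product (two or
more distinct products), then other. The ±60 min tolerance is a package
convention; the cascade makes multi-mechanism days deterministic and
every absolute finding receives exactly one cause.

## Triage rules

The pharmacist layer validates alert summaries per patient: absolute
alerts always yield a recommendation, with the reason chosen as the most
specific applicable row of the closed reason taxonomy (an enzyme inducer
alongside an over-5 g alert, alcoholism, age over 75, other inducers,
falling back to the plain maximum-dose reason). Relative alerts are
validated only below 60 kg: always below 50 kg, and between 50 and 60 kg
only in the presence of a hepatotoxicity risk factor (eGFR < 15 ml/min,
chronic alcohol use, enzyme inducers, age > 75, severe hepatic
impairment). A missing-weight alert persisting at least 48 h (a package
default; the original trigger is not documented) yields a documentation
recommendation. Three taxonomy reasons (`reserve_dose`, `not_scheduled`,
`other`) are representable in the I/O but never produced by
`triage_cohort()`: they encode chart-review knowledge about the *cause*
of an overdose that an alert summary does not carry.

An intervention is `not_assessable` iff discharge follows within 24 h of
the recommendation; the acceptance rate is
`100 * accepted / (total - not_assessable)`, rounded half-up. All printed
percentages in the package round half-up (`round_half_up()`), because the
published tables this mirrors do; base R's round-half-even would disagree
on exact halves.

## The synthetic cohort generator

`sim_config()` defaults *are* the study conditions: 84.2% oral / 15.8%
IV / 0.01% rectal administrations; 4.31% of weighed patients under 50 kg
and 17.71% under 60 kg; 7.8% of patients without a weight record; an
injected overdose day for 17.4% of patients with a cause mix of
87.9% / 8.7% / 2.9% over switch, out-of-schedule and duplicate; 30% of
patients older than 75. Where the source material is silent the package
fixes a value once and documents it here:

* **Severity split** (`high_dose_frac = 0.5`): half of injected
  route-switch days total 6 g (3 IV + 3 oral), half 5 g (2 IV + 3 oral).
  A realistic split would make > 5 g days about 2% of overdoses, leaving
  a 500-patient cohort with at most one or two high days — useless for
  band-wise comparison. Equal mass gives both severity bands enough
  events to estimate detection rates; it is a stress-testing choice, not
  a prevalence claim.
* **Stale-weight probability** (0.15): fraction of documented weights
  that predate admission by 15–60 days (an outpatient measurement carried
  over), making them stale with respect to every administration.
* **Forward dating** (0.1 per patient-day; the real-world frequency is
  undocumented): a selected day has exactly one administration charted
  1–60 min in advance, matching the described nursing shortcut of
  documenting the next due round early.
* **Baseline dosing grammar**: 1 g q6h/q8h/q12h and 0.5 g q6h at fixed
  clock slots. This keeps every non-injected calendar day at or below
  4 g, so retrospective findings on generator output occur *exactly* on
  the injected days — the ground-truth consistency property the tests
  assert. Administration times carry no jitter for the same reason: exact
  slot times make the negative controls provable rather than probable.
* **Routes** are drawn i.i.d. per baseline dose from the configured mix.
  Real patients keep one route for a course; the i.i.d. choice trades
  that realism for an exactly binomial recovery check. Injected
  route-switch patients instead follow IV-before-switch / oral-after
  courses, so the configured mix applies to the non-injected population.

All randomness flows from one seed through four named substreams (cohort,
injection, schedule, entry), so cohort-level changes do not silently
reshuffle injections.

What passing tests on generator output do **not** show: performance on
real data. The generator has no verbal orders, no transfers between
wards, no dose-amount typos beyond what tests construct explicitly, no
route changes outside the injected mechanism, and minute-exact schedule
adherence. The absolute patient counts of any real deployment are
properties of that hospital's cohort and are not reproduced here — only
the arithmetic relations between counts, and the direction of the
engine's degradation under forward dating, are.

## Problem sizes and numerical choices

The test suite and the acceptance script use cohorts of 150–2000 patients
(500 for the engine-degradation experiment, 2000 for rate recovery within
three standard errors), and 1000 random small streams for the
window-oracle equivalence property. Timestamps are timezone-naive local
hospital time stored as UTC `POSIXct` at minute resolution; window edges
compare exactly because minute-resolution epochs are integers in double
precision. `round_half_up()` adds an epsilon of 1e-9 before flooring to
absorb binary representation error in quotients. Ties among simultaneous
administrations: both doses fall in each other's window (the window is
closed on the right), and the interval to a same-minute dose is 0 min.

## Known limitations

* The engine's full-stream window idealization (above) slightly
  overstates what a latency-afflicted production agent would see.
* Episode semantics are not modeled: the agent re-fires on every
  qualifying administration rather than once per overdose episode, which
  matches a summary-accumulating production log but inflates alert counts
  relative to an episode-deduplicated system.
* Triage covers only reasons derivable from alerts plus stay metadata.
* The generator injects at most one overdose day per patient; multiple
  and same-stay repeated overdoses occur in real data and are measurable
  by the retrospective module, but are not part of the generator's
  ground truth.
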