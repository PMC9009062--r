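---
title: "Methods: rule-based HbA1c monitoring and alerting on psychiatric wards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based HbA1c monitoring and alerting on psychiatric wards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycalert)
```

## The clinical problem and the system model

Inpatients on acute psychiatric wards have high rates of undetected or
poorly monitored dysglycaemia, and HbA1c screening is easy to miss during
an admission focused on acute mental-health care. `glycalert` models the
alerting layer of an electronic clinical decision support system for this
setting as a deterministic replay over an EHR event stream. The event
stream has three kinds — admission, discharge, HbA1c laboratory report —
totally ordered by instant with a fixed tie-break (admission, then lab
report, then discharge), so that a result reported at the very instant of
discharge is still attributed to the stay.

Two rules generate alerts:

1. **New-result rule.** Every HbA1c report whose reporting instant falls
   inside an admission episode triggers exactly one alert. Deduplication is
   keyed on the laboratory report identifier, so duplicated feed rows or
   repeated replays cannot double-alert, and two distinct results on the
   same day alert twice by design (the rule is per result, not per day).
2. **Reminder rule.** An episode with no result reported *on or after
   admission* accrues reminder due-instants at admission + 4 days and every
   7 days thereafter, each surfaced at the next daily evaluation tick
   (default 09:00 UTC) while the patient remains admitted. Pre-admission
   historical results do not cancel reminders — they only populate the
   history summary — because an old result does not discharge the duty to
   screen on this admission.

Nothing is emitted after discharge, in either mode. In caseload
(outpatient roster) mode only the new-result rule is active, since the
4-day anchor is meaningless without an admission.

## Alert content

Each alert carries the patient identity (internal key, 10-digit national
patient number validated by the Modulus-11 check, full name), the latest
value in both IFCC (mmol/mol) and DCCT (%) units via the NGSP/IFCC master
relationship $\%\,=\,0.09148 \times \mathrm{mmol/mol} + 2.152$, the band,
a newest-first history capped at 10 entries, the threshold reference table,
and knowledge-base recommendations grouped by category (monitoring,
lifestyle, screening, pharmacological, referral, links). The severe band
always includes an urgent-referral item. A `known_diabetes` flag — an
explicit input, never inferred, since a well-controlled history is not
evident from the HbA1c level — adds medication-intensification advice.

## Tunable parameters

All tunables live in one YAML document (see
`system.file("extdata", "pathway-config.yaml", package = "glycalert")`):

| parameter | default | units | rationale |
|---|---|---|---|
| `pre_diabetes_min` | 42 | mmol/mol | NICE non-diabetic-hyperglycaemia cut-off |
| `diabetes_min` | 48 | mmol/mol | NICE diabetes diagnostic cut-off |
| `severe_min` | 86 | mmol/mol | ~10% DCCT, conventional decompensation trigger |
| `red_flag_min` | 42 | mmol/mol | any abnormal result shows red; may be set to 48 |
| `first_reminder_after_days` | 4 | days | screening window post-admission |
| `reminder_interval_days` | 7 | days | weekly re-screening cadence |
| `evaluation_time_of_day` | 09:00 | UTC clock time | daily batch evaluation tick |
| `history_limit` | 10 | entries | history summary cap |

Band lower edges are inclusive, matching the diagnostic convention that
diabetes is diagnosed at HbA1c ≥ 48 mmol/mol. Durations are exact 24-hour
multiples from the admission instant; the tick mechanism mirrors a
scheduled batch job, which is why reminder *emission* instants snap to the
next daily tick after the due instant. Whether a deployed system would
evaluate continuously or in daily batches is an open design choice; the
batch default is stated here as this package's choice.

## The synthetic cohort generator

`generate_cohort()` emulates only the features the rules consume:

* **Occupancy.** Per ward, a day-by-day bed process: day 0 starts at the
  occupancy target (default 85% of 18/19/23 beds), vacated beds are
  refilled by a Poisson admission stream with rate
  `beds × occupancy / mean_LOS`, and a bed stays blocked through the whole
  discharge day so stays never overlap even intraday. Length of stay is
  geometric with mean 21 days (memoryless — a defensible first-order model
  of acute psychiatric stays, though real LOS distributions are
  heavier-tailed).
* **Testing.** 60% of admissions have an HbA1c collected after a uniform
  0–6-day ordering delay, with a 2–24 h laboratory turnaround. 30% of
  patients carry 1–3 pre-admission historical results (30–365 days old).
* **Values.** Each patient draws a glycaemic state from the mixture 50%
  normal / 30% pre-diabetes range / 20% diabetes range, with the diabetes
  share split 15% diabetes / 5% severe — echoing the reported prevalence in
  South London psychosis populations of 20% diabetes with a further 30%
  dysglycaemia. Within-band values are truncated normals; neither the
  distributions nor the split is empirically fitted, and they are stated
  here as declared defaults, all configurable.
* **Timestamps** are whole seconds, because the JSONL interchange format is
  second-resolution and determinism is defined over serialized bytes.

What passing tests on this cohort do **not** show: robustness to messy
real-world identifier reconciliation, HL7/FHIR feed quirks, % -unit
results (the log is mmol/mol by contract), clock-zone drift, or clinical
validity of the recommendation wording. The generator exists to exercise
the temporal logic, not to model psychiatric epidemiology.

## The audit oracle and conformance reporting

`oracle_replay()` recomputes the expected alert multiset with nested loops
over episodes, results and reminder cycles, re-deriving banding from raw
threshold comparisons. It deliberately shares no code with
`process_events()`; equivalence between the two on seeded cohorts (exact
multiset equality of dedup keys and trigger instants) is therefore
evidence of correctness rather than tautology. `conformance_report()`
scores a run per validation standard — one alert per new result; 4-day
reminders; weekly follow-ups; history, banding, recommendation and
identity correctness; no spurious alerts; none after discharge — with
per-ward counts and a PASS column (PASS ⇔ Expected = Actual). Content
standards are audited on the built alert objects against the source
records, not on rendered strings; rendering correctness is covered by its
own deterministic-output and well-formedness tests.

## Numerical and degenerate-input choices

* Timestamps must carry an explicit UTC offset; naive instants are input
  errors, because reminder arithmetic across time zones must be
  unambiguous. All arithmetic is on UTC epoch seconds.
* A result reported exactly at a reminder's due instant cancels it (the
  report is processed before the tick at equal instants); a result at the
  instant of discharge is in scope; a reminder due exactly at the
  discharge instant is emitted.
* Duplicate report rows are dropped with a warning (first kept); a
  discharge without a matching open episode is an input error; overlapping
  episodes for one patient are rejected.
* An unroutable ward produces the alert with empty recipients plus a
  warning — alerts are never silently dropped for routing reasons.
* Re-admission restarts the reminder clock; the alerted-report set
  persists across episodes.
* Reminders have no cycle cap: a long untested stay keeps reminding
  weekly. A cap would be a one-line config addition but none is stated in
  the guidance this encodes.
* Time-shift invariance of alert counts holds for whole-day shifts; a
  sub-day shift can move a due instant across a daily tick relative to a
  discharge, which is inherent to batch-tick semantics, so the metamorphic
  test uses whole-day shifts.

## Problem sizes used in validation

The shipped validation uses a 3-ward (18/19/23 beds), 30-day cohort
(~1,400 occupied bed-days, ~130–150 alerts) for the audited month; twenty
independent cohorts (~28,000 bed-days in total) for engine/oracle
equivalence; a 1,000-bed, 60-day single-ward cohort (>2,000 first results)
for the band-mixture chi-square check; and stay lengths 0–120 days for the
reminder-cadence law. These sizes were chosen to exercise every rule path
many times over while keeping the whole suite comfortably interactive.

## Known limitations

* The recommendation knowledge base is schema-faithful but editorially
  minimal; deployment requires clinical sign-off of the wording against
  the locally approved pathway document.
* Real validation counts from a deployed system depend on that site's
  census and testing rates; this package reproduces the *structure* of
  such an evaluation (Expected = Actual across all standards), not any
  site's specific numbers.
* No SMTP delivery, EHR write-back, or live feed connectors: the outbox
  directory and JSONL streams are the integration surface.
* Type 1 and gestational pathways, medication dosing, and free-text
  processing of clinical notes are out of scope.
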