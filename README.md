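# glycalert

Rule-based HbA1c monitoring and alerting for inpatient mental health.

People with serious mental illness carry a substantially elevated burden of
type 2 diabetes and dysglycaemia, and physical-health screening on acute
psychiatric wards is inconsistently delivered. `glycalert` implements the
alerting core of an electronic clinical decision support system for this
setting as a testable, self-contained pipeline: it replays a time-ordered
electronic health record (EHR) event log — admissions, discharges, and
glycated haemoglobin (HbA1c) laboratory reports — and emits deduplicated,
guideline-annotated alerts to ward clinicians. It is aimed at health
informaticians building or validating monitoring-and-alerting interventions,
and at anyone who needs a reference implementation of admission-anchored
screening reminders with an independent audit oracle.

## The rules

Let an admission episode start at time $a$ and end at discharge time $d$
(possibly open), and let the daily evaluation tick run at a fixed clock time
(default 09:00 UTC). With HbA1c value $v$ in IFCC units (mmol/mol) and
configurable thresholds $\theta_{pre} < \theta_{dm} < \theta_{sev}$
(defaults 42 / 48 / 86, after NICE diagnostic cut-offs):

* **Banding.** $v < \theta_{pre}$: NORMAL; $\theta_{pre} \le v < \theta_{dm}$:
  PRE_DIABETES; $\theta_{dm} \le v < \theta_{sev}$: DIABETES;
  $v \ge \theta_{sev}$: SEVERE_DYSGLYCAEMIA (urgent specialist referral).
  Lower band edges are inclusive. Results at or above a configurable
  red-flag threshold (default $\theta_{pre}$) render in red.
* **New-result alerts.** Every HbA1c report with $a \le t_{reported} \le d$
  triggers exactly one alert carrying the value (mmol/mol and DCCT %), its
  band, the prior-result history (newest first, capped), embedded threshold
  reference values, and band-specific guideline recommendations.
* **Monitoring reminders.** If no result is reported on or after admission,
  reminders fall due at $a + 4\,\mathrm{days} + 7k\,\mathrm{days}$,
  $k = 0, 1, 2, \ldots$, each surfaced at the next daily tick while the
  patient is still admitted. An untested stay of $L$ days therefore yields
  $\max(0, \lfloor (L-4)/7 \rfloor + 1)$ reminders.
* **Suppression.** No alert of any kind after discharge; alerts are
  deduplicated per report (and per episode × due-instant for reminders), so
  replaying a log is idempotent.

A brute-force day-by-day oracle (`oracle_replay()`, sharing no code with the
engine) recomputes the expected alert multiset, and `conformance_report()`
scores a run per validation standard in Expected(n)/Actual(n) form.

## Worked example

```r
library(glycalert)
cfg    <- default_pathway_config()          # thresholds, reminder policy, KB, routing
params <- cohort_params(seed = 7)           # 3 wards (18/19/23 beds), 30 days
log    <- generate_cohort(params)
log
#> <ehr_log> 124 patients, 124 episodes, 155 HbA1c results, 350 events

res <- process_events(log, cfg, horizon = cohort_horizon(params))
table(alerts_summary(res$alerts)$type)
#> MONITORING_REMINDER          NEW_RESULT
#>                  77                  62

head(alerts_summary(res$alerts)[, c("type", "patient_id", "ward_id", "band", "red_flag")], 4)
#>         type patient_id ward_id         band red_flag
#> 1 NEW_RESULT      P0041  WARD_Y       NORMAL    FALSE
#> 2 NEW_RESULT      P0048  WARD_Y       NORMAL    FALSE
#> 3 NEW_RESULT      P0007  WARD_X PRE_DIABETES     TRUE
#> 4 NEW_RESULT      P0081  WARD_Z PRE_DIABETES     TRUE

rep <- conformance_report(
  oracle_replay(log, cfg, horizon = cohort_horizon(params)),
  res$alerts, log, cfg)
as.data.frame(rep)[c(1, 2, 10), c("standard", "expected_n", "actual_n", "pass")]
#>    standard expected_n actual_n pass
#> 1         1         62       62 TRUE
#> 2         2         49       49 TRUE
#> 10       10          0        0 TRUE
```

Row 1 counts one alert per in-scope new result, row 2 the four-day
reminders, row 10 alerts after discharge (always expected to be zero).
`write_outbox(res$alerts, "outbox")` renders each alert as `.txt` and
`.html` with raised results flagged in red.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/glycalert.R simulate --seed 7 --out events.jsonl
Rscript inst/cli/glycalert.R run      --events events.jsonl --out alerts.jsonl --outbox outbox
Rscript inst/cli/glycalert.R audit    --events events.jsonl --alerts alerts.jsonl --out report.csv
```

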