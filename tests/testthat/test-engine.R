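# The temporal alerting core: reminder schedules, event replay, dedup,
# discharge suppression, determinism.

cfg <- default_pathway_config()

test_that("reminder schedule follows the 4-day-then-weekly arithmetic", {
  pol <- cfg$reminder_policy
  ep_open <- list(admitted_at = day_at(0), discharged_at = NA)
  # no results, horizon day 20 -> due days 4, 11, 18 at 09:00
  due <- reminder_schedule(ep_open, NULL, pol, horizon = day_at(20))
  expect_equal(due, c(day_at(4), day_at(11), day_at(18)))
  # a result on day 1 cancels the whole schedule
  due <- reminder_schedule(ep_open, day_at(1, 10), pol, horizon = day_at(30))
  expect_length(due, 0L)
  # discharge day 9 truncates to the day-4 reminder only
  due <- reminder_schedule(list(admitted_at = day_at(0), discharged_at = day_at(9)),
                           NULL, pol, horizon = day_at(30))
  expect_equal(due, day_at(4))
  # pre-admission results do not cancel reminders
  due <- reminder_schedule(ep_open, day_at(-100), pol, horizon = day_at(10))
  expect_equal(due, day_at(4))
})

test_that("the worked three-patient scenario produces exactly five alerts", {
  res <- process_events(fx_worked_log(), cfg, horizon = day_at(20))
  s <- alerts_summary(res$alerts)
  expect_equal(nrow(s), 5L)
  expect_equal(sum(s$type == "NEW_RESULT"), 1L)
  a <- res$alerts[[which(s$type == "NEW_RESULT")]]
  expect_equal(a$patient_id, "P01")
  expect_equal(a$band, "DIABETES")
  expect_true(a$red_flag)
  expect_equal(a$triggered_at, day_at(1, 10))
  rem <- s[s$type == "MONITORING_REMINDER", ]
  expect_equal(rem$patient_id[rem$triggered_at == day_at(4)],
               c("P02", "P03"))
  expect_equal(rem$triggered_at[rem$patient_id == "P03"],
               c(day_at(4), day_at(11), day_at(18)))
})

test_that("no alert of any kind is emitted after discharge", {
  # result reported the day after discharge; reminders past discharge
  log <- ehr_log(rbind(fx_patient(1), fx_patient(2)),
                 rbind(fx_episode(1, day_at(0), day_at(2, 15)),
                       fx_episode(2, day_at(0), day_at(9, 8))),
                 fx_result(1, 1, 55, day_at(3, 10)))
  res <- process_events(log, cfg, horizon = day_at(15))
  s <- alerts_summary(res$alerts)
  expect_equal(nrow(s), 1L)
  expect_equal(s$type, "MONITORING_REMINDER")
  expect_equal(s$patient_id, "P02")
  expect_equal(audit_counts(res$alerts, log, cfg)$after_discharge, 0L)
})

test_that("a result at the instant of discharge is still in scope", {
  log <- ehr_log(fx_patient(1), fx_episode(1, day_at(0), day_at(2)),
                 fx_result(1, 1, 50, day_at(2)))
  res <- process_events(log, cfg, horizon = day_at(5))
  expect_equal(length(res$alerts), 1L)
  expect_equal(res$alerts[[1]]$type, "NEW_RESULT")
})

test_that("dedup keys are stable and per-report, not per-day", {
  log <- ehr_log(fx_patient(1), fx_episode(1, day_at(0)),
                 rbind(fx_result(1, 1, 50, day_at(1, 10)),
                       fx_result(1, 2, 52, day_at(1, 14))))
  res <- process_events(log, cfg, horizon = day_at(3))
  keys <- vapply(res$alerts, dedup_key, character(1))
  expect_equal(keys, c("R|R01-1", "R|R01-2"))  # two same-day results, two alerts
  res2 <- process_events(log, cfg, horizon = day_at(3))
  expect_equal(vapply(res2$alerts, dedup_key, character(1)), keys)
  expect_equal(length(union(keys, keys)), length(keys))
})

test_that("replay is deterministic and serialization byte-identical", {
  params <- cohort_params(seed = 11)
  log <- generate_cohort(params)
  hz <- cohort_horizon(params)
  r1 <- process_events(log, cfg, horizon = hz)
  r2 <- process_events(log, cfg, horizon = hz)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_alerts(r1$alerts, f1); write_alerts(r2$alerts, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every in-scope report alerts exactly once; identities always match", {
  for (seed in c(3, 4)) {
    params <- cohort_params(seed = seed)
    log <- generate_cohort(params)
    hz <- cohort_horizon(params)
    res <- process_events(log, cfg, horizon = hz)
    s <- alerts_summary(res$alerts)
    # exactly-once per in-scope report
    in_scope <- vapply(seq_len(nrow(log$results)), function(i) {
      r <- log$results[i, ]
      ep <- log$episodes[log$episodes$patient_id == r$patient_id, ]
      any(as.numeric(r$reported_at) >= as.numeric(ep$admitted_at) &
            (is.na(ep$discharged_at) |
               as.numeric(r$reported_at) <= as.numeric(ep$discharged_at))) &&
        as.numeric(r$reported_at) <= as.numeric(hz)
    }, logical(1))
    expect_equal(sort(s$key[s$type == "NEW_RESULT"]),
                 sort(paste0("R|", log$results$report_id[in_scope])))
    # zero identity mismatches against source records
    expect_equal(audit_counts(res$alerts, log, cfg)$identity_mismatches, 0L)
    # reminder cadence: first at +4d, then exactly weekly (due instants)
    rem <- s[s$type == "MONITORING_REMINDER", ]
    due <- vapply(strsplit(rem$key, "|", fixed = TRUE), `[`, character(1), 3)
    due_t <- as.numeric(glycalert:::parse_instant(due, "due"))
    adm <- as.numeric(log$episodes$admitted_at[
      match(rem$episode_id, log$episodes$episode_id)])
    offs <- (due_t - adm - 4 * 86400) / (7 * 86400)
    expect_true(all(abs(offs - round(offs)) < 1e-9))
  }
})

test_that("re-admission restarts the reminder clock", {
  e1 <- fx_episode(1, day_at(0), day_at(2))
  e2 <- fx_episode(1, day_at(10)); e2$episode_id <- "E91"
  log <- ehr_log(fx_patient(1), rbind(e1, e2))
  res <- process_events(log, cfg, horizon = day_at(16))
  s <- alerts_summary(res$alerts)
  # first stay too short for a reminder; second stay reminds at day 14
  expect_equal(nrow(s), 1L)
  expect_equal(s$episode_id, "E91")
  expect_equal(s$triggered_at, day_at(14))
})

test_that("caseload mode alerts on roster results only, no reminders", {
  roster <- data.frame(patient_id = c("P01", "P02"),
                       care_coordinator_email = c("cc1@example.nhs.uk",
                                                  "cc2@example.nhs.uk"),
                       stringsAsFactors = FALSE)
  log <- ehr_log(rbind(fx_patient(1), fx_patient(2), fx_patient(3)),
                 rbind(fx_episode(1, day_at(0)), fx_episode(2, day_at(0)),
                       fx_episode(3, day_at(0))),
                 rbind(fx_result(1, 1, 44, day_at(1, 10)),
                       fx_result(3, 1, 90, day_at(1, 11))))
  res <- process_events(log, cfg, horizon = day_at(20), mode = "caseload",
                        roster = roster)
  s <- alerts_summary(res$alerts)
  expect_equal(nrow(s), 1L)                       # P03 not on roster
  expect_equal(s$patient_id, "P01")
  expect_equal(s$type, "NEW_RESULT")
  expect_equal(res$alerts[[1]]$recipients, "cc1@example.nhs.uk")
})

test_that("unroutable wards still alert, with empty recipients and a warning", {
  log <- ehr_log(fx_patient(1), fx_episode(1, day_at(0), ward = "WARD_UNKNOWN"),
                 fx_result(1, 1, 50, day_at(1)))
  expect_warning(res <- process_events(log, cfg, horizon = day_at(2)),
                 "no routing entry")
  expect_equal(length(res$alerts), 1L)
  expect_equal(res$alerts[[1]]$recipients, character(0))
})

test_that("empty input yields empty output", {
  res <- process_events(ehr_log(), cfg)
  expect_equal(res$alerts, list())
  expect_equal(res$state$alerted_reports, character(0))
})
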