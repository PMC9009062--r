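# Domain model: identifier validation, log assembly, file round-trips.

test_that("NHS number validation implements the mod-11 check", {
  # check digit for 943476591: weighted sum 299, 299 %% 11 = 2, 11 - 2 = 9
  expect_true(validate_nhs_number("9434765919"))
  expect_false(validate_nhs_number("9434765918"))  # mismatched final digit
  expect_false(validate_nhs_number("12345"))       # wrong length
  expect_false(validate_nhs_number("943476591a"))
  expect_false(validate_nhs_number(NA_character_))
  expect_equal(validate_nhs_number(c("9434765919", "9434765918")),
               c(TRUE, FALSE))
})

test_that("naive timestamps are rejected, offsets accepted", {
  expect_error(glycalert:::parse_instant("2023-06-01T09:00:00", "t"),
               "explicit offset", class = "glycalert_input_error")
  z <- glycalert:::parse_instant("2023-06-01T09:00:00Z", "t")
  off <- glycalert:::parse_instant("2023-06-01T10:00:00+01:00", "t")
  expect_equal(as.numeric(z), as.numeric(off))  # same instant
})

test_that("log assembly sorts events with the documented tie-break", {
  # a result reported at the instant of discharge sorts before the discharge
  log <- ehr_log(fx_patient(1),
                 fx_episode(1, day_at(0), day_at(2)),
                 fx_result(1, 1, 50, day_at(2)))
  kinds <- log$events$kind
  expect_equal(kinds, c("ADMISSION", "HBA1C_REPORT", "DISCHARGE"))
})

test_that("log invariants are enforced", {
  expect_error(ehr_log(fx_patient(1), fx_episode(1, day_at(2), day_at(0))),
               "discharged_at precedes", class = "glycalert_input_error")
  # overlapping episodes for one patient
  e1 <- fx_episode(1, day_at(0), day_at(10))
  e2 <- fx_episode(1, day_at(5)); e2$episode_id <- "E99"
  expect_error(ehr_log(fx_patient(1), rbind(e1, e2)),
               "overlapping", class = "glycalert_input_error")
  # insane values and inverted result instants
  expect_error(ehr_log(fx_patient(1), fx_episode(1, day_at(0)),
                       fx_result(1, 1, 250, day_at(1))),
               "sane bounds", class = "glycalert_input_error")
  expect_error(ehr_log(fx_patient(1), fx_episode(1, day_at(0)),
                       fx_result(1, 1, 50, day_at(1), collected = day_at(2))),
               "precedes collected_at", class = "glycalert_input_error")
  # referential integrity
  expect_error(ehr_log(fx_patient(1), fx_episode(2, day_at(0))),
               "unknown patient", class = "glycalert_input_error")
})

test_that("duplicate report ids are dropped with a warning, first kept", {
  r <- rbind(fx_result(1, 1, 50, day_at(1)), fx_result(1, 1, 60, day_at(2)))
  expect_warning(
    log <- ehr_log(fx_patient(1), fx_episode(1, day_at(0)), r),
    "duplicate report_id")
  expect_equal(nrow(log$results), 1L)
  expect_equal(log$results$value, 50)
})

test_that("NHS validation on load is advisory by default, strict on request", {
  p <- fx_patient(1, nhs = "1234567890")  # fails mod-11
  expect_warning(ehr_log(p, fx_episode(1, day_at(0))), "invalid NHS number")
  expect_error(ehr_log(p, fx_episode(1, day_at(0)), nhs_check = "strict"),
               "invalid NHS number", class = "glycalert_input_error")
  expect_silent(ehr_log(p, fx_episode(1, day_at(0)), nhs_check = "none"))
})

test_that("JSONL event logs round-trip and read is idempotent", {
  log <- fx_worked_log()
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(log, f)
  log2 <- read_event_log(f)
  expect_equal(log2$events, log$events)
  expect_equal(log2$results, log$results)
  expect_equal(log2$episodes, log$episodes)
  log3 <- read_event_log(f)
  expect_identical(log2, log3)
})

test_that("empty sources give empty logs", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), f)
  log <- read_event_log(f)
  expect_equal(nrow(log$events), 0L)
})

test_that("events out of order on disk come back chronological", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"kind":"DISCHARGE","occurred_at":"2023-06-05T12:00:00+00:00","episode_id":"E01"}',
    '{"kind":"HBA1C_REPORT","occurred_at":"2023-06-02T10:00:00+00:00","report_id":"R1","patient_id":"P01","value":50,"collected_at":"2023-06-02T09:00:00+00:00","reported_at":"2023-06-02T10:00:00+00:00"}',
    '{"kind":"ADMISSION","occurred_at":"2023-06-01T09:00:00+00:00","episode_id":"E01","patient_id":"P01","ward_id":"WARD_X","nhs_number":"9434765919","full_name":"Test Patient 01"}'),
    f)
  log <- read_event_log(f)
  expect_equal(log$events$kind, c("ADMISSION", "HBA1C_REPORT", "DISCHARGE"))
  expect_false(is.unsorted(as.numeric(log$events$occurred_at)))
})

test_that("malformed rows raise input errors naming line and field", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"kind":"ADMISSION","occurred_at":"2023-06-01T09:00:00+00:00","episode_id":"E01","patient_id":"P01","ward_id":"W","nhs_number":"9434765919","full_name":"A"}',
    '{"kind":"HBA1C_REPORT","occurred_at":"2023-06-02T10:00:00+00:00","report_id":"R1"}'),
    f)
  expect_error(read_event_log(f), "line 2.*patient_id",
               class = "glycalert_input_error")

  writeLines('{"kind":"DISCHARGE","occurred_at":"2023-06-05T12:00:00+00:00","episode_id":"E77"}', f)
  expect_error(read_event_log(f), "unknown episode",
               class = "glycalert_input_error")

  writeLines('not json at all', f)
  expect_error(read_event_log(f), "line 1", class = "glycalert_input_error")
})

test_that("fuzzed malformed rows always raise the documented error, never crash", {
  set.seed(42)
  good <- '{"kind":"ADMISSION","occurred_at":"2023-06-01T09:00:00+00:00","episode_id":"E01","patient_id":"P01","ward_id":"W","nhs_number":"9434765919","full_name":"A"}'
  for (i in 1:30) {
    # random corruption: truncation, field deletion, garbage injection
    bad <- switch(sample(3, 1),
      substr(good, 1, sample(nchar(good) - 1, 1)),
      sub('"patient_id":"P01",', "", good, fixed = TRUE),
      paste0(good, sample(c("}", "{", "garbage"), 1)))
    f <- tempfile(fileext = ".jsonl")
    writeLines(bad, f)
    res <- tryCatch(read_event_log(f), condition = function(c) c)
    unlink(f)
    if (inherits(res, "ehr_log")) next  # corruption happened to stay valid
    expect_s3_class(res, "glycalert_error")
  }
})

test_that("CSV directory logs load equivalently to JSONL", {
  d <- withr::local_tempdir()
  write.csv(data.frame(episode_id = "E01", patient_id = "P01",
                       ward_id = "WARD_X", nhs_number = "9434765919",
                       full_name = "Test Patient 01",
                       admitted_at = "2023-06-01T09:00:00+00:00"),
            file.path(d, "admissions.csv"), row.names = FALSE)
  write.csv(data.frame(episode_id = "E01",
                       discharged_at = "2023-06-10T09:00:00+00:00"),
            file.path(d, "discharges.csv"), row.names = FALSE)
  write.csv(data.frame(report_id = "R1", patient_id = "P01", value = 50,
                       collected_at = "2023-06-02T09:00:00+00:00",
                       reported_at = "2023-06-02T10:00:00+00:00"),
            file.path(d, "hba1c.csv"), row.names = FALSE)
  log <- read_event_log(d, format = "csv")
  expect_equal(log$events$kind, c("ADMISSION", "HBA1C_REPORT", "DISCHARGE"))
  expect_equal(log$results$value, 50)
})

test_that("alert JSONL write/read is the identity, lines in trigger order", {
  cfg <- default_pathway_config()
  res <- process_events(fx_worked_log(), cfg, horizon = day_at(20))
  expect_gt(length(res$alerts), 1L)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_alerts(res$alerts, f)
  back <- read_alerts(f)
  expect_equal(back, res$alerts)
  t <- vapply(back, function(a) as.numeric(a$triggered_at), numeric(1))
  expect_false(is.unsorted(t))
  # empty sequence -> empty file
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_alerts(list(), f2)
  expect_equal(length(readLines(f2)), 0L)
  expect_equal(read_alerts(f2), list())
})
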