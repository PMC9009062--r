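# Alert assembly, rendering (text/HTML), routing, outbox.

cfg <- default_pathway_config()

mk_new_result_alert <- function(value = 44, history = NULL) {
  build_alert("NEW_RESULT", fx_patient(1), day_at(1, 10), cfg,
              episode_id = "E01", ward_id = "WARD_X",
              result = fx_result(1, 9, value, day_at(1, 10)),
              history = history, recipients = resolve_recipients("WARD_X", cfg$routing))
}

test_that("built alerts carry band, red flag, thresholds and capped history", {
  a <- mk_new_result_alert(44)
  expect_equal(a$band, "PRE_DIABETES")
  expect_true(a$red_flag)
  expect_equal(a$thresholds$diabetes_min, 48)
  expect_equal(a$value_percent, mmol_to_percent(44))
  expect_equal(nrow(a$history), 0L)

  hist <- do.call(rbind, lapply(1:12, function(k)
    fx_result(1, k, 40 + k, day_at(-400 + 10 * k))))
  a <- mk_new_result_alert(44, history = hist[, c("report_id", "value", "reported_at")])
  expect_equal(nrow(a$history), cfg$history_limit)       # capped at 10
  expect_false(is.unsorted(rev(as.numeric(a$history$reported_at))))  # newest first
  expect_equal(a$history$report_id[1], "R01-12")
})

test_that("reminder alerts have no latest result and monitoring guidance", {
  a <- build_alert("MONITORING_REMINDER", fx_patient(2), day_at(4), cfg,
                   episode_id = "E02", ward_id = "WARD_Y", due_at = day_at(4))
  expect_true(is.na(a$value))
  expect_true(is.na(a$band))
  expect_false(a$red_flag)
  expect_equal(nrow(a$history), 0L)
  expect_true("MONITORING" %in% a$recommendations$category)
  expect_equal(a$dedup_key, "M|E02|2023-06-05T09:00:00+00:00")
})

test_that("an unknown patient identity refuses to emit", {
  bad <- fx_patient(1)[0, ]
  expect_error(build_alert("MONITORING_REMINDER", bad, day_at(4), cfg,
                           due_at = day_at(4)),
               "guessed identity", class = "glycalert_integrity_error")
})

test_that("rendering is deterministic and red-flags exactly once", {
  raised <- mk_new_result_alert(44)
  normal <- mk_new_result_alert(35)
  expect_identical(render_alert(raised, "html"), render_alert(raised, "html"))
  expect_identical(render_alert(raised, "text"), render_alert(raised, "text"))

  h_raised <- render_alert(raised, "html")
  h_normal <- render_alert(normal, "html")
  count <- function(x, pat) lengths(gregexpr(pat, x, fixed = TRUE)) *
    grepl(pat, x, fixed = TRUE)
  expect_equal(count(h_raised, 'class="red-flag"'), 1L)
  expect_equal(count(h_normal, 'class="red-flag"'), 0L)
  expect_true(grepl("** RAISED **", render_alert(raised, "text"), fixed = TRUE))
  expect_false(grepl("** RAISED **", render_alert(normal, "text"), fixed = TRUE))
})

test_that("documents carry the patient header exactly once, plus content blocks", {
  hist <- fx_result(1, 2, 39, day_at(-30))
  a <- mk_new_result_alert(50, history = hist[, c("report_id", "value", "reported_at")])
  for (fmt in c("text", "html")) {
    doc <- render_alert(a, fmt)
    expect_equal(lengths(gregexpr(a$nhs_number, doc, fixed = TRUE)), 1L)
    expect_equal(lengths(gregexpr(a$full_name, doc, fixed = TRUE)), 1L)
    expect_true(grepl("threshold", doc, ignore.case = TRUE))
    expect_true(grepl("39", doc))                     # history value shown
    expect_true(grepl("mmol/mol", doc))
  }
})

test_that("HTML output is well-formed for a spread of fixture alerts", {
  skip_if_not_installed("xml2")
  res <- process_events(scenario("S5_banding")$log, cfg,
                        horizon = scenario("S5_banding")$horizon)
  rem <- build_alert("MONITORING_REMINDER", fx_patient(2), day_at(4), cfg,
                     episode_id = "E02", ward_id = "WARD_Y", due_at = day_at(4))
  for (a in c(res$alerts, list(rem))) {
    doc <- xml2::read_html(render_alert(a, "html"))
    expect_s3_class(doc, "xml_document")
  }
})

test_that("no rendered document leaks another patient's identifiers", {
  sc <- scenario("S8_no_leakage")
  res <- process_events(sc$log, cfg, horizon = sc$horizon)
  pats <- sc$log$patients
  for (a in res$alerts) {
    others <- pats[pats$patient_id != a$patient_id, ]
    for (fmt in c("text", "html")) {
      doc <- render_alert(a, fmt)
      expect_false(any(vapply(others$nhs_number, grepl, logical(1), x = doc,
                              fixed = TRUE)))
      expect_false(any(vapply(others$full_name, grepl, logical(1), x = doc,
                              fixed = TRUE)))
    }
  }
})

test_that("recipient resolution: known ward, unknown ward, caseload roster", {
  expect_equal(resolve_recipients("WARD_X", cfg$routing),
               c("ward.x.clinician1@example.nhs.uk",
                 "ward.x.clinician2@example.nhs.uk"))
  expect_warning(r <- resolve_recipients("NOWHERE", cfg$routing),
                 "no routing entry")
  expect_equal(r, character(0))
  roster <- data.frame(patient_id = "P09",
                       care_coordinator_email = "cc@example.nhs.uk")
  expect_equal(glycalert:::resolve_recipients_caseload("P09", roster),
               "cc@example.nhs.uk")
  expect_equal(glycalert:::resolve_recipients_caseload("P10", roster),
               character(0))
})

test_that("the outbox holds one txt+html per alert and a manifest", {
  res <- process_events(fx_worked_log(), cfg, horizon = day_at(20))
  d <- withr::local_tempdir()
  write_outbox(res$alerts, d)
  idx <- read.csv(file.path(d, "index.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(idx), length(res$alerts))
  for (id in idx$alert_id) {
    expect_true(file.exists(file.path(d, paste0(id, ".txt"))))
    expect_true(file.exists(file.path(d, paste0(id, ".html"))))
  }
  expect_false(is.unsorted(idx$triggered_at))
})
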