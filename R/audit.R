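# Independent audit harness: a deliberately naive day-by-day replay oracle
# (no shared code with the event-driven engine) and a conformance report in
# the Expected(n)/Actual(n)-per-standard format used for in-silico
# validation of alerting systems.

#' Brute-force oracle replay
#'
#' Recomputes the expected alert multiset by literal transcription of the
#' validation standards: nested loops over episodes, results and reminder
#' cycles, with banding re-derived from raw threshold comparisons. The
#' implementation intentionally shares no code with [process_events()], so
#' agreement between the two is evidence, not tautology.
#'
#' @param log an [ehr_log()].
#' @param config a `pathway_config`.
#' @param horizon `POSIXct` end of the evaluation window.
#' @param mode `"inpatient"` or `"caseload"`.
#' @param roster caseload roster (see [process_events()]).
#' @return data.frame of expected alerts: `key`, `type`, `patient_id`,
#'   `episode_id`, `ward_id`, `triggered_at`, `band`, `red_flag`,
#'   `n_history`.
#' @export
oracle_replay <- function(log, config = default_pathway_config(), horizon = NULL,
                          mode = c("inpatient", "caseload"), roster = NULL) {
  stopifnot(inherits(log, "ehr_log"))
  mode <- match.arg(mode)
  if (is.null(horizon)) {
    horizon <- if (nrow(log$events)) max(log$events$occurred_at)
               else as.POSIXct(0, tz = "UTC", origin = "1970-01-01")
  }
  hz <- as.numeric(horizon)
  th <- config$thresholds
  pol <- config$reminder_policy

  band_of <- function(v) {
    if (v < th$pre_diabetes_min) "NORMAL"
    else if (v < th$diabetes_min) "PRE_DIABETES"
    else if (v < th$severe_min) "DIABETES"
    else "SEVERE_DYSGLYCAEMIA"
  }
  n_hist <- function(pid, t) {
    min(sum(log$results$patient_id == pid &
              as.numeric(log$results$reported_at) < t),
        config$history_limit)
  }
  # first daily evaluation tick at or after instant x (ticks live at the
  # policy clock time on each UTC date)
  tick_after <- function(x) {
    base <- as.numeric(tick_on_date(as.Date(format(
      as.POSIXct(x, tz = "UTC", origin = "1970-01-01"), "%Y-%m-%d", tz = "UTC")),
      pol$evaluation_tod))
    if (base >= x) base else base + 86400
  }

  rows <- list()
  add <- function(key, type, pid, eid, ward, t, band, red, nh) {
    rows[[length(rows) + 1L]] <<- data.frame(
      key = key, type = type, patient_id = pid, episode_id = eid,
      ward_id = ward,
      triggered_at = as.POSIXct(t, tz = "UTC", origin = "1970-01-01"),
      band = band, red_flag = red, n_history = as.integer(nh),
      stringsAsFactors = FALSE)
  }

  if (mode == "caseload") {
    for (i in seq_len(nrow(log$results))) {
      r <- log$results[i, ]
      if (!r$patient_id %in% roster$patient_id) next
      if (as.numeric(r$reported_at) > hz) next
      add(paste0("R|", r$report_id), "NEW_RESULT", r$patient_id,
          NA_character_, NA_character_, as.numeric(r$reported_at),
          band_of(r$value), r$value >= th$red_flag_min,
          n_hist(r$patient_id, as.numeric(r$reported_at)))
    }
  } else {
    for (i in seq_len(nrow(log$episodes))) {
      ep <- log$episodes[i, ]
      adm <- as.numeric(ep$admitted_at)
      dis <- if (is.na(ep$discharged_at)) Inf else as.numeric(ep$discharged_at)

      pres <- log$results[log$results$patient_id == ep$patient_id, , drop = FALSE]
      rep_t <- as.numeric(pres$reported_at)

      # standard: one alert per new result reported while on the ward
      # (a result at the instant of discharge is still in scope)
      for (j in seq_len(nrow(pres))) {
        t <- rep_t[j]
        if (t >= adm && t <= dis && t <= hz) {
          add(paste0("R|", pres$report_id[j]), "NEW_RESULT", ep$patient_id,
              ep$episode_id, ep$ward_id, t, band_of(pres$value[j]),
              pres$value[j] >= th$red_flag_min, n_hist(ep$patient_id, t))
        }
      }

      # standards: first reminder after 4 days, weekly thereafter, only
      # while admitted and only until a new result arrives
      new_t <- rep_t[rep_t >= adm]
      first_new <- if (length(new_t)) min(new_t) else Inf
      k <- 0L
      repeat {
        due <- adm + pol$first_reminder_after + k * pol$reminder_interval
        if (due > hz || due > dis || due >= first_new) break
        emit_at <- tick_after(due)
        if (emit_at <= hz && emit_at <= dis && emit_at < first_new) {
          add(paste0("M|", ep$episode_id, "|",
                     format_instant(as.POSIXct(due, tz = "UTC",
                                               origin = "1970-01-01"))),
              "MONITORING_REMINDER", ep$patient_id, ep$episode_id, ep$ward_id,
              emit_at, NA_character_, FALSE, n_hist(ep$patient_id, emit_at))
        }
        k <- k + 1L
      }
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    key = character(), type = character(), patient_id = character(),
    episode_id = character(), ward_id = character(),
    triggered_at = as.POSIXct(character(), tz = "UTC"),
    band = character(), red_flag = logical(), n_history = integer(),
    stringsAsFactors = FALSE)
  out <- out[order(as.numeric(out$triggered_at), out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Summarise a list of engine alerts into the oracle's tabular shape.
#' Tabular summary of engine alerts
#'
#' @param alerts list of `glyc_alert` objects.
#' @return data.frame matching the [oracle_replay()] column layout.
#' @export
alerts_summary <- function(alerts) {
  if (!length(alerts)) {
    return(oracle_replay(ehr_log()))
  }
  out <- do.call(rbind, lapply(alerts, function(a) data.frame(
    key = a$dedup_key, type = a$type, patient_id = a$patient_id,
    episode_id = a$episode_id, ward_id = a$ward_id,
    triggered_at = a$triggered_at, band = a$band, red_flag = a$red_flag,
    n_history = nrow(a$history), stringsAsFactors = FALSE)))
  out <- out[order(as.numeric(out$triggered_at), out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Counts used directly by the audit and the acceptance checks. All are
# measured against the source records, never trusted from the alert itself.
#' Audit counts over a run
#'
#' Computes, against the source event log: the number of alerts triggered
#' after their episode's discharge (expected 0), the number of alerts whose
#' patient name, NHS number or HbA1c value disagrees with the source
#' records (expected 0), and the number whose embedded history summary
#' disagrees with an independent recomputation.
#'
#' @param alerts list of `glyc_alert` objects from [process_events()].
#' @param log the [ehr_log()] the alerts were produced from.
#' @param config the `pathway_config` used.
#' @return named list of integer counts: `n_alerts`, `after_discharge`,
#'   `identity_mismatches`, `history_mismatches`, `red_flagged`.
#' @export
audit_counts <- function(alerts, log, config = default_pathway_config()) {
  fl <- audit_flags(alerts, log, config)
  list(n_alerts = nrow(fl),
       after_discharge = sum(fl$after_discharge),
       identity_mismatches = sum(!fl$identity_ok),
       history_mismatches = sum(!fl$history_ok),
       red_flagged = sum(fl$red_flag))
}

# Per-alert audit flags, each measured against the source log.
audit_flags <- function(alerts, log, config) {
  rows <- lapply(alerts, function(a) {
    after <- FALSE
    if (!is.na(a$episode_id)) {
      ep <- log$episodes[log$episodes$episode_id == a$episode_id, ]
      after <- nrow(ep) == 1L && !is.na(ep$discharged_at) &&
        as.numeric(a$triggered_at) > as.numeric(ep$discharged_at)
    }
    p <- log$patients[log$patients$patient_id == a$patient_id, ]
    ok_id <- nrow(p) == 1L && identical(p$nhs_number, a$nhs_number) &&
      identical(p$full_name, a$full_name)
    band_ok <- TRUE
    if (a$type == "NEW_RESULT") {
      r <- log$results[log$results$report_id == a$report_id, ]
      ok_id <- ok_id && nrow(r) == 1L && isTRUE(r$value == a$value) &&
        identical(r$patient_id, a$patient_id)
      band_ok <- identical(a$band, classify_band(a$value, config$thresholds)) &&
        identical(a$red_flag, unname(is_red_flag(a$value, config$thresholds)))
    }
    h <- log$results[log$results$patient_id == a$patient_id &
                       as.numeric(log$results$reported_at) <
                         as.numeric(a$triggered_at), , drop = FALSE]
    h <- h[order(as.numeric(h$reported_at), h$report_id, decreasing = TRUE), ,
           drop = FALSE]
    h <- utils::head(h, config$history_limit)
    hist_ok <- identical(as.character(h$report_id),
                         as.character(a$history$report_id))
    data.frame(ward_id = a$ward_id, type = a$type,
               after_discharge = after, identity_ok = ok_id,
               band_ok = band_ok, history_ok = hist_ok,
               recs_ok = nrow(a$recommendations) >= 1L,
               red_flag = isTRUE(a$red_flag), key = a$dedup_key,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(ward_id = character(), type = character(),
                      after_discharge = logical(), identity_ok = logical(),
                      band_ok = logical(), history_ok = logical(),
                      recs_ok = logical(), red_flag = logical(),
                      key = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

.STANDARD_DESCRIPTIONS <- c(
  "One alert per new HbA1c result reported for a patient on a test ward",
  "One reminder if no new HbA1c result 4 days post-admission",
  "Weekly reminders thereafter while no HbA1c result is reported",
  "Alerts include a summary of previous HbA1c reports where present",
  "New-result alerts state the value and its threshold band",
  "Alerts carry recommended actions in line with the clinical algorithm",
  "Alerts contain factually correct clinical and identifier information",
  "Alerts contain no incorrect clinical information or identifiers",
  "Alerts are only triggered per the algorithm (none unexpected)",
  "No alerts are triggered after discharge from the ward")

.INITIAL_DESCRIPTIONS <- c(
  "Alert triggered once an HbA1c result is available",
  "Alert received by the end user (non-empty recipients)",
  "Alert content clinically correct for the correct patient",
  "Alert content incorrect or mis-identified",
  "Alert contains HbA1c threshold reference information",
  "Alert flags the result in red if raised above threshold")

#' Conformance report (Expected vs Actual per standard)
#'
#' Scores an engine run against the oracle expectation, one row per
#' validation standard, with per-ward actual counts, Expected(n), Actual(n)
#' and a PASS column (PASS iff Expected = Actual). Inpatient mode scores the
#' ten in-silico standards; caseload mode the six initial (outpatient)
#' standards.
#'
#' @param expected [oracle_replay()] output for the same log and config.
#' @param alerts engine alerts from [process_events()].
#' @param log the shared [ehr_log()].
#' @param config the shared `pathway_config`.
#' @param mode `"inpatient"` or `"caseload"`.
#' @return data.frame of class `conformance_report`.
#' @export
conformance_report <- function(expected, alerts, log,
                               config = default_pathway_config(),
                               mode = c("inpatient", "caseload")) {
  mode <- match.arg(mode)
  actual <- alerts_summary(alerts)
  if (nrow(expected) && nrow(actual) &&
      !all(actual$patient_id %in% c(log$patients$patient_id))) {
    integrity_error("actual alerts reference patients absent from the audited log")
  }
  counts <- audit_counts(alerts, log, config)
  policy <- config$reminder_policy

  # classify reminders into first (4-day) vs weekly follow-ups
  rem_is_first <- function(df) {
    if (!nrow(df)) return(logical(0L))
    adm <- as.numeric(log$episodes$admitted_at[
      match(df$episode_id, log$episodes$episode_id)])
    due <- vapply(strsplit(df$key, "|", fixed = TRUE), function(x) {
      if (length(x) == 3L) as.numeric(parse_instant(x[3L], "due")) else NA_real_
    }, numeric(1L))
    abs(due - (adm + policy$first_reminder_after)) < 1e-6
  }

  exp_new <- expected[expected$type == "NEW_RESULT", , drop = FALSE]
  act_new <- actual[actual$type == "NEW_RESULT", , drop = FALSE]
  exp_rem <- expected[expected$type == "MONITORING_REMINDER", , drop = FALSE]
  act_rem <- actual[actual$type == "MONITORING_REMINDER", , drop = FALSE]

  sig <- function(df) paste(df$key, format_instant(df$triggered_at))
  multiset_equal <- nrow(expected) == nrow(actual) &&
    identical(sort(sig(expected)), sort(sig(actual)))
  n_matching <- length(intersect(sig(expected), sig(actual)))

  # per-row expected/actual totals
  fl <- audit_flags(alerts, log, config)
  if (mode == "inpatient") {
    exp_tot <- c(nrow(exp_new), sum(rem_is_first(exp_rem)),
                 sum(!rem_is_first(exp_rem)), nrow(expected), nrow(exp_new),
                 nrow(expected), nrow(expected), 0L, nrow(expected), 0L)
    act_tot <- c(nrow(act_new), sum(rem_is_first(act_rem)),
                 sum(!rem_is_first(act_rem)),
                 sum(fl$history_ok),
                 sum(fl$type == "NEW_RESULT" & fl$band_ok),
                 sum(fl$recs_ok),
                 sum(fl$identity_ok),
                 sum(!fl$identity_ok),
                 if (multiset_equal) counts$n_alerts else n_matching,
                 counts$after_discharge)
    desc <- .STANDARD_DESCRIPTIONS
  } else {
    has_recip <- vapply(alerts, function(a) length(a$recipients) > 0L, logical(1L))
    has_thresh <- vapply(alerts, function(a) length(a$thresholds) == 4L, logical(1L))
    exp_tot <- c(nrow(expected), nrow(expected), nrow(expected), 0L,
                 nrow(expected), sum(expected$red_flag))
    act_tot <- c(nrow(actual), sum(has_recip),
                 counts$n_alerts - counts$identity_mismatches,
                 counts$identity_mismatches, sum(has_thresh),
                 counts$red_flagged)
    desc <- .INITIAL_DESCRIPTIONS
  }

  report <- data.frame(standard = seq_along(desc), description = desc,
                       stringsAsFactors = FALSE)
  wards <- sort(unique(stats::na.omit(log$episodes$ward_id)))
  if (mode == "inpatient") {
    for (w in wards) {
      in_w <- !is.na(fl$ward_id) & fl$ward_id == w
      fw <- fl[in_w, , drop = FALSE]
      is_first <- rem_is_first(
        actual[in_w & actual$type == "MONITORING_REMINDER", , drop = FALSE])
      report[[w]] <- c(sum(fw$type == "NEW_RESULT"), sum(is_first),
                       sum(!is_first), sum(fw$history_ok),
                       sum(fw$type == "NEW_RESULT" & fw$band_ok),
                       sum(fw$recs_ok), sum(fw$identity_ok),
                       sum(!fw$identity_ok),
                       sum(fw$key %in% expected$key),
                       sum(fw$after_discharge))
    }
  }
  report$expected_n <- as.integer(exp_tot)
  report$actual_n <- as.integer(act_tot)
  report$pass <- report$expected_n == report$actual_n
  class(report) <- c("conformance_report", "data.frame")
  report
}

#' @export
print.conformance_report <- function(x, ...) {
  cat("Conformance report (Expected vs Actual per standard)\n")
  df <- as.data.frame(x)
  df$description <- substr(df$description, 1, 52)
  print(df, row.names = FALSE, right = FALSE)
  cat(if (all(x$pass)) "All standards PASS\n"
      else sprintf("%d standard(s) FAIL\n", sum(!x$pass)))
  invisible(x)
}

#' Write a conformance report to CSV
#'
#' @param report a `conformance_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_conformance_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
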