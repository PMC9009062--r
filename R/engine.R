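# The temporal alerting core. A deterministic replay of the event stream,
# interleaved with daily evaluation ticks, that emits:
#
#  * one NEW_RESULT alert per HbA1c report whose patient is in scope
#    (inpatient mode: currently admitted; caseload mode: on the roster),
#  * MONITORING_REMINDER alerts for admitted patients with no new result,
#    first at 4 days post-admission and weekly thereafter (configurable),
#
# with per-report deduplication and full suppression after discharge.
#
# "New result" means reported_at >= admitted_at of the current episode:
# pre-admission historical results never cancel reminders, they only
# populate the history summary in the alert.

#' Reminder due instants for one admission episode
#'
#' Due instants are `admitted_at + first_reminder_after + k * interval` for
#' `k = 0, 1, 2, ...` (exact 24-hour days), truncated at
#' `min(horizon, discharged_at)` and truncated entirely at the `reported_at`
#' of the first new result (a result reported on or after admission).  The
#' engine surfaces each due instant at the next daily evaluation tick.
#'
#' @param episode list or one-row data.frame with `admitted_at` and
#'   optionally `discharged_at` (`NA` = still admitted).
#' @param results the patient's HbA1c results: a data.frame with
#'   `reported_at`, or a `POSIXct` vector of report instants.
#' @param policy a [reminder_policy()].
#' @param horizon `POSIXct` end of the evaluation window.
#' @return `POSIXct` vector of due instants (possibly empty).
#' @export
reminder_schedule <- function(episode, results = NULL,
                              policy = reminder_policy(), horizon) {
  admitted <- as.POSIXct(episode$admitted_at, tz = "UTC")
  discharged <- episode$discharged_at %||% NA
  discharged <- as.POSIXct(discharged, tz = "UTC")
  stopifnot(length(admitted) == 1L, !is.na(admitted))
  end <- as.numeric(horizon)
  if (length(discharged) == 1L && !is.na(discharged)) {
    end <- min(end, as.numeric(discharged))
  }
  rep_at <- if (is.null(results)) as.POSIXct(character(), tz = "UTC")
            else if (inherits(results, "POSIXct")) results
            else as.POSIXct(results$reported_at, tz = "UTC")
  new_at <- as.numeric(rep_at)[as.numeric(rep_at) >= as.numeric(admitted)]
  if (length(new_at)) end <- min(end, min(new_at) - 1e-6)  # result cancels its own due instant
  first <- as.numeric(admitted) + policy$first_reminder_after
  if (first > end) return(as.POSIXct(numeric(), tz = "UTC", origin = "1970-01-01"))
  due <- seq(first, end, by = policy$reminder_interval)
  as.POSIXct(due, tz = "UTC", origin = "1970-01-01")
}

# Daily evaluation tick instants covering [start, horizon].
evaluation_ticks <- function(start, horizon, policy) {
  if (as.numeric(horizon) < as.numeric(start)) {
    return(as.POSIXct(numeric(), tz = "UTC", origin = "1970-01-01"))
  }
  d0 <- as.Date(format(start, "%Y-%m-%d", tz = "UTC"))
  d1 <- as.Date(format(horizon, "%Y-%m-%d", tz = "UTC"))
  ticks <- tick_on_date(seq(d0, d1, by = "day"), policy$evaluation_tod)
  ticks[as.numeric(ticks) <= as.numeric(horizon)]
}

#' Replay an event log and emit alerts
#'
#' Deterministic replay: events are interleaved with daily evaluation ticks
#' (at the policy's `evaluation_time_of_day`) up to `horizon`. At equal
#' instants the order is ADMISSION, HBA1C_REPORT, evaluation tick,
#' DISCHARGE — so a result reported at the instant of discharge is still in
#' scope, and a result landing exactly on a tick cancels that tick's
#' reminder. No alert of any kind is emitted after discharge. Replaying the
#' same inputs yields the identical alert sequence (alert ids derive from
#' the dedup key).
#'
#' @param log an [ehr_log()].
#' @param config a `pathway_config` from [load_pathway_config()].
#' @param horizon `POSIXct` end of the evaluation window; defaults to the
#'   last event instant.
#' @param mode `"inpatient"` (admission-anchored reminders active) or
#'   `"caseload"` (outpatient roster monitoring; new-result alerts only).
#' @param roster caseload mode only: data.frame with `patient_id` and
#'   optionally `care_coordinator_email` and `known_diabetes`.
#' @return list with `alerts` (list of `glyc_alert`, in trigger order) and
#'   `state` (open episodes, alerted report ids, last reminder instants).
#' @export
process_events <- function(log, config = default_pathway_config(),
                           horizon = NULL, mode = c("inpatient", "caseload"),
                           roster = NULL) {
  stopifnot(inherits(log, "ehr_log"))
  mode <- match.arg(mode)
  if (!inherits(config, "pathway_config")) config_error("config must be a pathway_config")
  if (mode == "caseload" && is.null(roster)) config_error("caseload mode needs a roster")
  policy <- config$reminder_policy
  ev <- log$events
  if (is.unsorted(as.numeric(ev$occurred_at))) input_error("event stream is not chronologically ordered")
  if (is.null(horizon)) {
    horizon <- if (nrow(ev)) max(ev$occurred_at) else as.POSIXct(0, tz = "UTC", origin = "1970-01-01")
  }
  horizon <- as.POSIXct(horizon, tz = "UTC")

  ev <- ev[as.numeric(ev$occurred_at) <= as.numeric(horizon), , drop = FALSE]
  agenda <- data.frame(
    time = as.numeric(ev$occurred_at),
    rank = unname(.KIND_RANK[ev$kind]),
    kind = ev$kind, key = ev$key, patient_id = ev$patient_id,
    stringsAsFactors = FALSE)
  if (mode == "inpatient" && nrow(ev)) {
    ticks <- evaluation_ticks(min(ev$occurred_at), horizon, policy)
    if (length(ticks)) {
      agenda <- rbind(agenda, data.frame(
        time = as.numeric(ticks), rank = 2.5, kind = "TICK",
        key = format_instant(ticks), patient_id = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  agenda <- agenda[order(agenda$time, agenda$rank, agenda$key), , drop = FALSE]

  # engine state
  open <- list()            # patient_id -> list(episode_id, ward_id, admitted_at, next_due, new_result)
  alerted <- character()    # report_ids already alerted on
  last_reminder <- list()   # episode_id -> POSIXct
  warned_wards <- character()
  alerts <- list(); n_alerts <- 0L
  push <- function(a) {
    n_alerts <<- n_alerts + 1L
    alerts[[n_alerts]] <<- a
  }

  resolve_ward <- function(ward_id) {
    addr <- config$routing$wards[[ward_id]]
    if (is.null(addr)) {
      if (!ward_id %in% warned_wards) {
        warned_wards <<- c(warned_wards, ward_id)
        glyc_warn("no routing entry for ward '%s'; alert emitted with empty recipients", ward_id)
      }
      return(character())
    }
    as.character(unlist(addr))
  }

  history_before <- function(pid, t) {
    h <- log$results[log$results$patient_id == pid &
                       as.numeric(log$results$reported_at) < as.numeric(t), ,
                     drop = FALSE]
    h[, c("report_id", "value", "reported_at")]
  }

  roster_known <- function(pid) {
    if (is.null(roster) || is.null(roster$known_diabetes)) return(FALSE)
    isTRUE(as.logical(roster$known_diabetes[match(pid, roster$patient_id)]))
  }

  for (i in seq_len(nrow(agenda))) {
    kind <- agenda$kind[i]
    t <- as.POSIXct(agenda$time[i], tz = "UTC", origin = "1970-01-01")

    if (kind == "ADMISSION") {
      e <- log$episodes[log$episodes$episode_id == agenda$key[i], ]
      open[[e$patient_id]] <- list(
        episode_id = e$episode_id, ward_id = e$ward_id,
        admitted_at = e$admitted_at,
        next_due = as.numeric(e$admitted_at) + policy$first_reminder_after,
        new_result = FALSE)

    } else if (kind == "DISCHARGE") {
      e <- log$episodes[log$episodes$episode_id == agenda$key[i], ]
      st <- open[[e$patient_id]]
      if (!is.null(st) && identical(st$episode_id, e$episode_id)) {
        open[[e$patient_id]] <- NULL
      }

    } else if (kind == "HBA1C_REPORT") {
      r <- log$results[log$results$report_id == agenda$key[i], ]
      pid <- r$patient_id
      st <- open[[pid]]
      in_scope <- if (mode == "inpatient") {
        !is.null(st) && as.numeric(t) >= as.numeric(st$admitted_at)
      } else {
        pid %in% roster$patient_id
      }
      if (mode == "inpatient" && !is.null(st) &&
          as.numeric(t) >= as.numeric(st$admitted_at)) {
        open[[pid]]$new_result <- TRUE
      }
      if (in_scope && !r$report_id %in% alerted) {
        alerted <- c(alerted, r$report_id)
        recipients <- if (mode == "inpatient") resolve_ward(st$ward_id)
                      else resolve_recipients_caseload(pid, roster)
        push(build_alert(
          "NEW_RESULT",
          patient = log$patients[log$patients$patient_id == pid, ],
          triggered_at = t, config = config,
          episode_id = if (mode == "inpatient") st$episode_id else NA_character_,
          ward_id = if (mode == "inpatient") st$ward_id else NA_character_,
          result = r, history = history_before(pid, t),
          known_diabetes = roster_known(pid), recipients = recipients))
      }

    } else {  # TICK: reminder evaluation for every open, untested episode
      for (pid in names(open)) {
        st <- open[[pid]]
        if (st$new_result) next
        while (st$next_due <= agenda$time[i]) {
          due <- as.POSIXct(st$next_due, tz = "UTC", origin = "1970-01-01")
          push(build_alert(
            "MONITORING_REMINDER",
            patient = log$patients[log$patients$patient_id == pid, ],
            triggered_at = t, config = config,
            episode_id = st$episode_id, ward_id = st$ward_id,
            history = history_before(pid, t), due_at = due,
            recipients = resolve_ward(st$ward_id)))
          last_reminder[[st$episode_id]] <- t
          st$next_due <- st$next_due + policy$reminder_interval
          open[[pid]] <- st
        }
      }
    }
  }

  alerts <- alerts[seq_len(n_alerts)]
  if (length(alerts)) {
    ord <- order(vapply(alerts, function(a) as.numeric(a$triggered_at), numeric(1L)),
                 vapply(alerts, function(a) a$dedup_key, character(1L)))
    alerts <- alerts[ord]
  }
  keys <- vapply(alerts, dedup_key, character(1L))
  if (anyDuplicated(keys)) integrity_error("duplicate alert dedup key: %s",
                                           keys[duplicated(keys)][1L])
  list(alerts = alerts,
       state = list(open_episodes = open, alerted_reports = alerted,
                    last_reminder = last_reminder, mode = mode,
                    horizon = horizon))
}
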