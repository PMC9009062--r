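# The Alert object: the clinical payload of one triggered notification,
# plus JSONL persistence with a stable field order and round-trip fidelity.

.ALERT_TYPES <- c("NEW_RESULT", "MONITORING_REMINDER")

#' Build an alert from a validated trigger context
#'
#' Assembles the full clinical payload for one trigger: patient identity,
#' the latest result with band and red-flag status (for new-result alerts),
#' the prior-result history (newest first, capped at the configured limit),
#' the embedded threshold reference values, and the guideline
#' recommendations for the band (or the monitoring-reminder set).
#'
#' @param type `"NEW_RESULT"` or `"MONITORING_REMINDER"`.
#' @param patient one-row data.frame (patient_id, nhs_number, full_name).
#' @param triggered_at trigger instant (`POSIXct`).
#' @param config a `pathway_config` from [load_pathway_config()].
#' @param episode_id,ward_id episode context; `NA` in caseload mode.
#' @param result one-row results data.frame for the triggering report
#'   (`NULL` for reminders).
#' @param history data.frame of prior results (report_id, value,
#'   reported_at), any order; sorted newest-first and capped here.
#' @param due_at reminder due instant (reminders only; part of the dedup
#'   key).
#' @param known_diabetes logical, documented diabetes history.
#' @param recipients character vector of destination addresses.
#' @return a `glyc_alert` object.
#' @export
build_alert <- function(type, patient, triggered_at, config,
                        episode_id = NA_character_, ward_id = NA_character_,
                        result = NULL, history = NULL, due_at = NULL,
                        known_diabetes = FALSE, recipients = character()) {
  if (!type %in% .ALERT_TYPES) input_error("unknown alert type '%s'", type)
  if (is.null(patient) || nrow(patient) != 1L || is.na(patient$patient_id)) {
    integrity_error("alert trigger for unknown patient: refusing to emit with guessed identity")
  }
  th <- config$thresholds

  if (is.null(history) || nrow(history) == 0L) {
    history <- data.frame(report_id = character(), value = numeric(),
                          reported_at = as.POSIXct(character(), tz = "UTC"),
                          stringsAsFactors = FALSE)
  } else {
    history <- history[order(history$reported_at, history$report_id,
                             decreasing = TRUE), , drop = FALSE]
    history <- utils::head(history, config$history_limit)
  }
  history <- data.frame(report_id = as.character(history$report_id),
                        value = as.numeric(history$value),
                        band = if (nrow(history)) classify_band(history$value, th) else character(),
                        reported_at = history$reported_at,
                        stringsAsFactors = FALSE)
  rownames(history) <- NULL

  if (type == "NEW_RESULT") {
    stopifnot(!is.null(result), nrow(result) == 1L)
    band <- classify_band(result$value, th)
    red <- is_red_flag(result$value, th)
    recs <- recommendations_for(band, known_diabetes, config$knowledge_base)
    dedup <- paste0("R|", result$report_id)
    report_id <- result$report_id
    value <- result$value
  } else {
    if (is.null(due_at)) input_error("reminder alert needs its due instant")
    band <- NA_character_; red <- FALSE
    recs <- recommendations_for("reminder", FALSE, config$knowledge_base)
    dedup <- paste0("M|", episode_id, "|", format_instant(due_at))
    report_id <- NA_character_
    value <- NA_real_
  }

  structure(
    list(
      alert_id = gsub("[^A-Za-z0-9]+", "-", dedup),
      type = type,
      patient_id = patient$patient_id,
      nhs_number = patient$nhs_number,
      full_name = patient$full_name,
      episode_id = episode_id,
      ward_id = ward_id,
      triggered_at = triggered_at,
      report_id = report_id,
      value = value,
      value_percent = if (is.na(value)) NA_real_ else mmol_to_percent(value),
      band = band,
      red_flag = red,
      history = history,
      thresholds = list(pre_diabetes_min = th$pre_diabetes_min,
                        diabetes_min = th$diabetes_min,
                        severe_min = th$severe_min,
                        red_flag_min = th$red_flag_min),
      recommendations = recs,
      recipients = as.character(recipients),
      dedup_key = dedup
    ),
    class = "glyc_alert"
  )
}

#' @export
print.glyc_alert <- function(x, ...) {
  cat(sprintf("<alert %s> %s %s (%s) at %s%s\n", x$alert_id, x$type,
              x$full_name, x$patient_id, format_instant(x$triggered_at),
              if (!is.na(x$value)) sprintf(" value=%g band=%s%s", x$value, x$band,
                                           if (x$red_flag) " RED" else "")
              else ""))
  invisible(x)
}

#' Stable deduplication key of an alert
#'
#' New-result alerts are keyed on the triggering `report_id`; monitoring
#' reminders on the episode and the reminder's due instant. The same
#' logical trigger therefore maps to the same key across runs, which is how
#' replays stay exactly-once.
#'
#' @param alert a `glyc_alert`.
#' @return the key string.
#' @export
dedup_key <- function(alert) {
  stopifnot(inherits(alert, "glyc_alert"))
  alert$dedup_key
}

# ---------------------------------------------------------------------------
# JSONL persistence

alert_to_json <- function(a) {
  nullable <- function(x) if (length(x) == 1L && is.na(x)) NULL else x
  rec <- list(
    alert_id = a$alert_id,
    type = a$type,
    patient_id = a$patient_id,
    nhs_number = a$nhs_number,
    full_name = a$full_name,
    episode_id = nullable(a$episode_id),
    ward_id = nullable(a$ward_id),
    triggered_at = format_instant(a$triggered_at),
    report_id = nullable(a$report_id),
    value = nullable(a$value),
    value_percent = nullable(a$value_percent),
    band = nullable(a$band),
    red_flag = a$red_flag,
    history = lapply(seq_len(nrow(a$history)), function(i) {
      list(report_id = a$history$report_id[i], value = a$history$value[i],
           band = a$history$band[i],
           reported_at = format_instant(a$history$reported_at[i]))
    }),
    thresholds = a$thresholds,
    recommendations = lapply(seq_len(nrow(a$recommendations)), function(i) {
      list(category = a$recommendations$category[i],
           text = a$recommendations$text[i])
    }),
    recipients = as.list(a$recipients),
    dedup_key = a$dedup_key
  )
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write alerts to a JSONL file
#'
#' One JSON object per line, fields in a stable order, timestamps as
#' ISO-8601 with explicit offset, lines in trigger-instant order.
#' [read_alerts()] is the exact inverse.
#'
#' @param alerts list of `glyc_alert` objects.
#' @param sink output file path.
#' @return `sink`, invisibly.
#' @export
write_alerts <- function(alerts, sink) {
  ok <- tryCatch({ con <- file(sink, open = "wt"); TRUE },
                 error = function(e) FALSE)
  if (!ok) io_error("cannot open alert sink for writing: %s", sink)
  on.exit(close(con))
  if (length(alerts)) {
    ord <- order(vapply(alerts, function(a) as.numeric(a$triggered_at), numeric(1L)),
                 vapply(alerts, function(a) a$dedup_key, character(1L)))
    alerts <- alerts[ord]
    for (a in alerts) writeLines(alert_to_json(a), con)
  }
  invisible(sink)
}

#' @rdname write_alerts
#' @param source JSONL file written by [write_alerts()].
#' @return `read_alerts()`: list of `glyc_alert` objects.
#' @export
read_alerts <- function(source) {
  if (!file.exists(source)) io_error("alert file not found: %s", source)
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec)) input_error("line %d: malformed alert row", i)
    de_null <- function(x, na) if (is.null(x)) na else x
    hist <- rec$history
    history <- data.frame(
      report_id = vapply(hist, function(h) h$report_id, character(1L)),
      value = vapply(hist, function(h) as.numeric(h$value), numeric(1L)),
      band = vapply(hist, function(h) h$band, character(1L)),
      reported_at = parse_instant(vapply(hist, function(h) h$reported_at,
                                         character(1L)), "reported_at"),
      stringsAsFactors = FALSE)
    recs <- data.frame(
      category = vapply(rec$recommendations, function(r) r$category, character(1L)),
      text = vapply(rec$recommendations, function(r) r$text, character(1L)),
      stringsAsFactors = FALSE)
    structure(
      list(alert_id = rec$alert_id, type = rec$type,
           patient_id = rec$patient_id, nhs_number = rec$nhs_number,
           full_name = rec$full_name,
           episode_id = de_null(rec$episode_id, NA_character_),
           ward_id = de_null(rec$ward_id, NA_character_),
           triggered_at = parse_instant(rec$triggered_at, "triggered_at"),
           report_id = de_null(rec$report_id, NA_character_),
           value = as.numeric(de_null(rec$value, NA_real_)),
           value_percent = as.numeric(de_null(rec$value_percent, NA_real_)),
           band = de_null(rec$band, NA_character_),
           red_flag = isTRUE(rec$red_flag),
           history = history,
           thresholds = lapply(rec$thresholds, as.numeric),
           recommendations = recs,
           recipients = vapply(rec$recipients, as.character, character(1L)),
           dedup_key = rec$dedup_key),
      class = "glyc_alert")
  })
}
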