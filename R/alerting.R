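# Rendering of alerts into human-readable notifications (plain text and
# HTML) and recipient routing. Messages are written to an outbox directory
# rather than dispatched over SMTP: the clinical contribution is the content
# and triggering, transport is deployment-specific.

#' Resolve alert recipients for a ward
#'
#' Looks up the ward's clinician addresses in the routing configuration.
#' An unknown ward yields an empty address list with a warning — alerts are
#' never silently dropped for routing reasons.
#'
#' @param ward_id ward identifier.
#' @param routing the `routing` element of a `pathway_config`.
#' @return character vector of addresses (possibly empty).
#' @export
resolve_recipients <- function(ward_id, routing = default_pathway_config()$routing) {
  addr <- routing$wards[[ward_id]]
  if (is.null(addr)) {
    glyc_warn("no routing entry for ward '%s'", ward_id)
    return(character())
  }
  as.character(unlist(addr))
}

# Caseload mode routes per patient to the care coordinator on the roster.
resolve_recipients_caseload <- function(patient_id, roster) {
  if (is.null(roster$care_coordinator_email)) return(character())
  addr <- roster$care_coordinator_email[match(patient_id, roster$patient_id)]
  if (is.na(addr)) character() else as.character(addr)
}

fmt_val <- function(value) {
  sprintf("%s mmol/mol (%s%%)", format(value), format(mmol_to_percent(value)))
}

#' Render an alert as a document
#'
#' Produces, in order: the patient header (full name, NHS number, exactly
#' once each); the alert type heading; for new-result alerts the latest
#' value in both mmol/mol and DCCT % with its band statement; the
#' prior-result history table; the threshold reference block; the
#' recommendation items grouped by category; and guideline links. In HTML
#' the latest value is wrapped in a red-styled `<span class="red-flag">`
#' if and only if the alert is red-flagged; in text it is prefixed with the
#' configured marker (default `** RAISED **`). Rendering is deterministic.
#'
#' @param alert a `glyc_alert`.
#' @param format `"text"` or `"html"`.
#' @param red_flag_marker text-mode prefix for raised values.
#' @return a single document string.
#' @export
render_alert <- function(alert, format = c("text", "html"),
                         red_flag_marker = "** RAISED **") {
  stopifnot(inherits(alert, "glyc_alert"))
  format <- match.arg(format)
  if (format == "text") render_alert_text(alert, red_flag_marker)
  else render_alert_html(alert)
}

band_statement <- function(alert) {
  switch(alert$band,
    NORMAL = "within the normal range",
    PRE_DIABETES = "in the pre-diabetes (non-diabetic hyperglycaemia) range",
    DIABETES = "at or above the diabetes diagnostic threshold",
    SEVERE_DYSGLYCAEMIA = "in the severe dysglycaemia range - urgent specialist referral indicated")
}

threshold_lines <- function(th) {
  c(sprintf("  Normal:               below %g mmol/mol", th$pre_diabetes_min),
    sprintf("  Pre-diabetes:         %g to below %g mmol/mol",
            th$pre_diabetes_min, th$diabetes_min),
    sprintf("  Diabetes:             %g to below %g mmol/mol",
            th$diabetes_min, th$severe_min),
    sprintf("  Severe dysglycaemia:  %g mmol/mol and above", th$severe_min))
}

render_alert_text <- function(a, marker) {
  lines <- c(
    "=== Glycaemic monitoring alert ===",
    sprintf("Patient: %s", a$full_name),
    sprintf("NHS number: %s", a$nhs_number),
    if (!is.na(a$ward_id)) sprintf("Ward: %s", a$ward_id),
    sprintf("Triggered: %s", format_instant(a$triggered_at)),
    "",
    if (a$type == "NEW_RESULT") {
      c("-- New HbA1c result --",
        sprintf("Latest HbA1c: %s%s", if (a$red_flag) paste0(marker, " ") else "",
                fmt_val(a$value)),
        sprintf("This result is %s.", band_statement(a)))
    } else {
      "-- HbA1c monitoring reminder --"
    },
    "",
    "Previous HbA1c results:",
    if (nrow(a$history)) {
      sprintf("  %s  %s  (%s)", format_instant(a$history$reported_at),
              fmt_val(a$history$value), a$history$band)
    } else "  none on record",
    "",
    "HbA1c threshold reference:",
    threshold_lines(a$thresholds),
    "",
    "Recommended actions:")
  for (cat in unique(a$recommendations$category)) {
    lines <- c(lines, sprintf("[%s]", cat),
               sprintf("  - %s", a$recommendations$text[a$recommendations$category == cat]))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_alert_html <- function(a) {
  val <- function(v) html_escape(fmt_val(v))
  latest <- if (a$type == "NEW_RESULT") {
    v <- if (a$red_flag) {
      sprintf('<span class="red-flag" style="color:#c00000;font-weight:bold">%s</span>',
              val(a$value))
    } else val(a$value)
    c("<h2>New HbA1c result</h2>",
      sprintf("<p>Latest HbA1c: %s</p>", v),
      sprintf("<p>This result is %s.</p>", html_escape(band_statement(a))))
  } else {
    "<h2>HbA1c monitoring reminder</h2>"
  }
  hist <- if (nrow(a$history)) {
    c("<table><tr><th>Reported</th><th>HbA1c</th><th>Band</th></tr>",
      sprintf("<tr><td>%s</td><td>%s</td><td>%s</td></tr>",
              format_instant(a$history$reported_at), val(a$history$value),
              html_escape(a$history$band)),
      "</table>")
  } else "<p>None on record.</p>"
  recs <- character()
  for (cat in unique(a$recommendations$category)) {
    recs <- c(recs, sprintf("<h4>%s</h4><ul>", html_escape(cat)),
              sprintf("<li>%s</li>",
                      html_escape(a$recommendations$text[a$recommendations$category == cat])),
              "</ul>")
  }
  paste(c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/><title>Glycaemic monitoring alert</title></head>",
    "<body>",
    "<h1>Glycaemic monitoring alert</h1>",
    sprintf("<p>Patient: %s<br/>NHS number: %s%s<br/>Triggered: %s</p>",
            html_escape(a$full_name), html_escape(a$nhs_number),
            if (!is.na(a$ward_id)) sprintf("<br/>Ward: %s", html_escape(a$ward_id)) else "",
            format_instant(a$triggered_at)),
    latest,
    "<h3>Previous HbA1c results</h3>", hist,
    "<h3>HbA1c threshold reference</h3>",
    "<ul>", sprintf("<li>%s</li>", html_escape(trimws(threshold_lines(a$thresholds)))), "</ul>",
    "<h3>Recommended actions</h3>", recs,
    "</body></html>"), collapse = "\n")
}

#' Write rendered alerts to an outbox directory
#'
#' One `.txt` and one `.html` document per alert (file stem = alert id),
#' plus an `index.csv` manifest (alert_id, patient_id, type, triggered_at,
#' recipients, semicolon-separated).
#'
#' @param alerts list of `glyc_alert` objects.
#' @param dir outbox directory (created if needed).
#' @param red_flag_marker passed to [render_alert()].
#' @return `dir`, invisibly.
#' @export
write_outbox <- function(alerts, dir, red_flag_marker = "** RAISED **") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (length(alerts)) {
    ord <- order(vapply(alerts, function(a) as.numeric(a$triggered_at), numeric(1L)),
                 vapply(alerts, function(a) a$dedup_key, character(1L)))
    alerts <- alerts[ord]
  }
  idx <- data.frame(
    alert_id = vapply(alerts, function(a) a$alert_id, character(1L)),
    patient_id = vapply(alerts, function(a) a$patient_id, character(1L)),
    type = vapply(alerts, function(a) a$type, character(1L)),
    triggered_at = vapply(alerts, function(a) format_instant(a$triggered_at), character(1L)),
    recipients = vapply(alerts, function(a) paste(a$recipients, collapse = ";"), character(1L)),
    stringsAsFactors = FALSE)
  for (a in alerts) {
    writeLines(render_alert(a, "text", red_flag_marker),
               file.path(dir, paste0(a$alert_id, ".txt")), sep = "")
    writeLines(render_alert(a, "html"),
               file.path(dir, paste0(a$alert_id, ".html")))
  }
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}
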