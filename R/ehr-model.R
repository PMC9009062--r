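# EHR domain model: patients, admission episodes, HbA1c results, and the
# time-ordered event log the alerting engine replays.  File formats are
# deliberately plain (JSONL, RFC-4180 CSV); there is no live EHR connection.

.EVENT_KINDS <- c("ADMISSION", "HBA1C_REPORT", "DISCHARGE")
# Tie-break rank when occurred_at coincides: a result reported at the instant
# of discharge is still attributed to the stay.
.KIND_RANK <- c(ADMISSION = 1L, HBA1C_REPORT = 2L, DISCHARGE = 3L)

#' Validate an NHS number
#'
#' An NHS number is a 10-digit national patient identifier whose final digit
#' is a Modulus 11 check digit: digits 1-9 are weighted 10 down to 2, summed,
#' and the remainder mod 11 subtracted from 11 gives the check value (11 maps
#' to 0; a check value of 10 means the number is invalid).
#'
#' @param candidate character vector of candidate numbers.
#' @return logical vector, `TRUE` where the candidate is a well-formed NHS
#'   number with a correct check digit. Non-conforming strings (wrong length,
#'   non-digits, `NA`) return `FALSE`; the function never errors.
#' @examples
#' validate_nhs_number("9434765919")  # TRUE
#' validate_nhs_number("9434765918")  # FALSE (check digit mismatch)
#' @export
validate_nhs_number <- function(candidate) {
  vapply(as.character(candidate), function(x) {
    if (is.na(x) || !grepl("^[0-9]{10}$", x)) return(FALSE)
    d <- as.integer(strsplit(x, "")[[1L]])
    chk <- nhs_check_digit(d[1:9])
    !is.na(chk) && chk == d[10L]
  }, logical(1L), USE.NAMES = FALSE)
}

# Check digit for a 9-digit prefix; NA when the check value is 10 (no valid
# NHS number has that prefix).
nhs_check_digit <- function(digits9) {
  s <- sum(digits9 * (10:2))
  chk <- 11L - (s %% 11L)
  if (chk == 11L) chk <- 0L
  if (chk == 10L) return(NA_integer_)
  chk
}

# ---------------------------------------------------------------------------
# Log assembly and validation

#' Assemble and validate an EHR event log
#'
#' Combines the three record tables into a single chronologically ordered
#' event stream (one ADMISSION and, where discharged, one DISCHARGE event per
#' episode; one HBA1C_REPORT event per result, occurring at `reported_at`).
#' Ties on `occurred_at` are broken ADMISSION < HBA1C_REPORT < DISCHARGE,
#' then lexicographically by record key, so replays are deterministic.
#'
#' All type invariants are enforced here: positive sane HbA1c values
#' (0 < value < 200 mmol/mol), `reported_at >= collected_at`,
#' `discharged_at >= admitted_at`, unique keys, non-overlapping episodes per
#' patient, and referential integrity from results/episodes to patients.
#' Duplicate `report_id` rows are dropped with a warning (first kept).
#'
#' @param patients data.frame with columns `patient_id`, `nhs_number`,
#'   `full_name` and optionally `date_of_birth`.
#' @param episodes data.frame with columns `episode_id`, `patient_id`,
#'   `ward_id`, `admitted_at`, `discharged_at` (`NA` = still admitted).
#' @param results data.frame with columns `report_id`, `patient_id`, `value`
#'   (mmol/mol, IFCC), `collected_at`, `reported_at`.
#' @param nhs_check `"warn"` (default) flags malformed NHS numbers with a
#'   warning, `"strict"` makes them an error, `"none"` skips the check.
#'   Advisory by default because synthetic fixtures may use arbitrary digits.
#' @return an object of class `ehr_log`: a list with elements `patients`,
#'   `episodes`, `results` and the ordered `events` table.
#' @export
ehr_log <- function(patients = NULL, episodes = NULL, results = NULL,
                    nhs_check = c("warn", "strict", "none")) {
  nhs_check <- match.arg(nhs_check)
  patients <- normalise_patients(patients)
  episodes <- normalise_episodes(episodes)
  results  <- normalise_results(results)

  if (anyDuplicated(patients$patient_id)) {
    input_error("duplicate patient_id: %s",
                patients$patient_id[duplicated(patients$patient_id)][1L])
  }
  if (nhs_check != "none" && nrow(patients)) {
    ok <- validate_nhs_number(patients$nhs_number)
    if (any(!ok)) {
      msg <- sprintf("%d patient(s) with invalid NHS number (first: %s)",
                     sum(!ok), patients$nhs_number[which(!ok)[1L]])
      if (nhs_check == "strict") input_error("%s", msg) else glyc_warn("%s", msg)
    }
  }

  if (anyDuplicated(episodes$episode_id)) {
    input_error("duplicate episode_id: %s",
                episodes$episode_id[duplicated(episodes$episode_id)][1L])
  }
  unknown <- setdiff(episodes$patient_id, patients$patient_id)
  if (length(unknown)) {
    input_error("episode references unknown patient_id: %s", unknown[1L])
  }
  bad <- !is.na(episodes$discharged_at) & episodes$discharged_at < episodes$admitted_at
  if (any(bad)) {
    input_error("episode %s: discharged_at precedes admitted_at",
                episodes$episode_id[which(bad)[1L]])
  }
  check_no_overlap(episodes)

  dup <- duplicated(results$report_id)
  if (any(dup)) {
    glyc_warn("%d duplicate report_id row(s) dropped (first occurrence kept; first: %s)",
              sum(dup), results$report_id[which(dup)[1L]])
    results <- results[!dup, , drop = FALSE]
  }
  unknown <- setdiff(results$patient_id, patients$patient_id)
  if (length(unknown)) {
    input_error("HbA1c result references unknown patient_id: %s", unknown[1L])
  }
  bad <- results$value <= 0 | results$value >= 200
  if (any(bad)) {
    input_error("result %s: HbA1c value %s mmol/mol outside sane bounds (0, 200)",
                results$report_id[which(bad)[1L]], results$value[which(bad)[1L]])
  }
  bad <- results$reported_at < results$collected_at
  if (any(bad)) {
    input_error("result %s: reported_at precedes collected_at",
                results$report_id[which(bad)[1L]])
  }

  structure(
    list(patients = patients, episodes = episodes, results = results,
         events = build_events(episodes, results)),
    class = "ehr_log"
  )
}

normalise_patients <- function(p) {
  if (is.null(p) || nrow(as.data.frame(p)) == 0L) {
    return(data.frame(patient_id = character(), nhs_number = character(),
                      full_name = character(), date_of_birth = character(),
                      stringsAsFactors = FALSE))
  }
  p <- as.data.frame(p, stringsAsFactors = FALSE)
  need_cols(p, c("patient_id", "nhs_number", "full_name"), "patients")
  if (is.null(p$date_of_birth)) p$date_of_birth <- NA_character_
  data.frame(patient_id = as.character(p$patient_id),
             nhs_number = as.character(p$nhs_number),
             full_name = as.character(p$full_name),
             date_of_birth = as.character(p$date_of_birth),
             stringsAsFactors = FALSE)
}

normalise_episodes <- function(e) {
  if (is.null(e) || nrow(as.data.frame(e)) == 0L) {
    return(data.frame(episode_id = character(), patient_id = character(),
                      ward_id = character(),
                      admitted_at = as.POSIXct(character(), tz = "UTC"),
                      discharged_at = as.POSIXct(character(), tz = "UTC"),
                      stringsAsFactors = FALSE))
  }
  e <- as.data.frame(e, stringsAsFactors = FALSE)
  need_cols(e, c("episode_id", "patient_id", "ward_id", "admitted_at"), "episodes")
  if (is.null(e$discharged_at)) e$discharged_at <- NA_character_
  data.frame(episode_id = as.character(e$episode_id),
             patient_id = as.character(e$patient_id),
             ward_id = as.character(e$ward_id),
             admitted_at = as_instant_col(e$admitted_at, "admitted_at"),
             discharged_at = as_instant_col(e$discharged_at, "discharged_at",
                                            allow_na = TRUE),
             stringsAsFactors = FALSE)
}

normalise_results <- function(r) {
  if (is.null(r) || nrow(as.data.frame(r)) == 0L) {
    return(data.frame(report_id = character(), patient_id = character(),
                      value = numeric(),
                      collected_at = as.POSIXct(character(), tz = "UTC"),
                      reported_at = as.POSIXct(character(), tz = "UTC"),
                      stringsAsFactors = FALSE))
  }
  r <- as.data.frame(r, stringsAsFactors = FALSE)
  need_cols(r, c("report_id", "patient_id", "value", "collected_at", "reported_at"),
            "results")
  v <- suppressWarnings(as.numeric(r$value))
  if (anyNA(v)) input_error("field 'value': non-numeric HbA1c value")
  data.frame(report_id = as.character(r$report_id),
             patient_id = as.character(r$patient_id),
             value = v,
             collected_at = as_instant_col(r$collected_at, "collected_at"),
             reported_at = as_instant_col(r$reported_at, "reported_at"),
             stringsAsFactors = FALSE)
}

as_instant_col <- function(x, field, allow_na = FALSE) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    if (!allow_na && anyNA(x)) input_error("field '%s': missing instant", field)
    return(x)
  }
  x <- as.character(x)
  if (allow_na) {
    out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC", origin = "1970-01-01")
    has <- !is.na(x) & nzchar(x)
    if (any(has)) out[has] <- parse_instant(x[has], field)
    return(out)
  }
  parse_instant(x, field)
}

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    input_error("%s table missing column(s): %s", what, paste(miss, collapse = ", "))
  }
}

check_no_overlap <- function(episodes) {
  for (pid in unique(episodes$patient_id)) {
    e <- episodes[episodes$patient_id == pid, , drop = FALSE]
    if (nrow(e) < 2L) next
    e <- e[order(e$admitted_at), , drop = FALSE]
    ends <- e$discharged_at
    # an open episode extends to the end of the horizon
    ends[is.na(ends)] <- as.POSIXct(Inf, tz = "UTC", origin = "1970-01-01")
    if (any(e$admitted_at[-1L] < ends[-nrow(e)])) {
      input_error("patient %s has overlapping admission episodes", pid)
    }
  }
  invisible(TRUE)
}

build_events <- function(episodes, results) {
  ev <- rbind(
    data.frame(kind = rep("ADMISSION", nrow(episodes)),
               occurred_at = episodes$admitted_at,
               key = episodes$episode_id,
               patient_id = episodes$patient_id, stringsAsFactors = FALSE),
    {
      disch <- episodes[!is.na(episodes$discharged_at), , drop = FALSE]
      data.frame(kind = rep("DISCHARGE", nrow(disch)),
                 occurred_at = disch$discharged_at,
                 key = disch$episode_id,
                 patient_id = disch$patient_id, stringsAsFactors = FALSE)
    },
    data.frame(kind = rep("HBA1C_REPORT", nrow(results)),
               occurred_at = results$reported_at,
               key = results$report_id,
               patient_id = results$patient_id, stringsAsFactors = FALSE)
  )
  ord <- order(ev$occurred_at, .KIND_RANK[ev$kind], ev$key)
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' @export
print.ehr_log <- function(x, ...) {
  cat(sprintf("<ehr_log> %d patients, %d episodes, %d HbA1c results, %d events\n",
              nrow(x$patients), nrow(x$episodes), nrow(x$results), nrow(x$events)))
  if (nrow(x$events)) {
    cat(sprintf("  span: %s .. %s\n",
                format_instant(min(x$events$occurred_at)),
                format_instant(max(x$events$occurred_at))))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Readers / writers

#' Read an EHR event log from disk
#'
#' `format = "jsonl"` expects one JSON event object per line with a `kind`
#' field (`ADMISSION`, `DISCHARGE`, `HBA1C_REPORT`), an `occurred_at` instant,
#' and kind-specific fields (admission events embed the patient identity).
#' `format = "csv"` expects a directory containing `admissions.csv`,
#' `discharges.csv` and `hba1c.csv`, RFC-4180 with a header row.  Events are
#' returned sorted chronologically regardless of on-disk order.
#'
#' @param source file path (jsonl) or directory path (csv).
#' @param format `"jsonl"` or `"csv"`.
#' @param nhs_check passed to [ehr_log()].
#' @return an [ehr_log()] object.
#' @export
read_event_log <- function(source, format = c("jsonl", "csv"),
                           nhs_check = "warn") {
  format <- match.arg(format)
  if (!file.exists(source)) io_error("event log source not found: %s", source)
  if (format == "jsonl") read_event_log_jsonl(source, nhs_check)
  else read_event_log_csv(source, nhs_check)
}

read_event_log_jsonl <- function(path, nhs_check) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pat <- list(); epi <- list(); res <- list(); disch <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$kind)) {
      input_error("line %d: malformed event row (field 'kind')", i)
    }
    kind <- as.character(rec$kind)
    if (!kind %in% .EVENT_KINDS) {
      input_error("line %d: unknown event kind '%s' (field 'kind')", i, kind)
    }
    fields <- switch(kind,
      ADMISSION = c("occurred_at", "episode_id", "patient_id", "ward_id",
                    "nhs_number", "full_name"),
      DISCHARGE = c("occurred_at", "episode_id"),
      HBA1C_REPORT = c("occurred_at", "report_id", "patient_id", "value",
                       "collected_at", "reported_at"))
    miss <- fields[!vapply(fields, function(f) !is.null(rec[[f]]), logical(1L))]
    if (length(miss)) {
      input_error("line %d: malformed %s row (field '%s')", i, kind, miss[[1L]])
    }
    if (kind == "ADMISSION") {
      pat[[length(pat) + 1L]] <- data.frame(
        patient_id = as.character(rec$patient_id),
        nhs_number = as.character(rec$nhs_number),
        full_name = as.character(rec$full_name),
        date_of_birth = as.character(rec$date_of_birth %||% NA_character_),
        stringsAsFactors = FALSE)
      epi[[length(epi) + 1L]] <- data.frame(
        episode_id = as.character(rec$episode_id),
        patient_id = as.character(rec$patient_id),
        ward_id = as.character(rec$ward_id),
        admitted_at = as.character(rec$occurred_at),
        discharged_at = NA_character_, stringsAsFactors = FALSE)
    } else if (kind == "DISCHARGE") {
      disch[[length(disch) + 1L]] <- data.frame(
        episode_id = as.character(rec$episode_id),
        discharged_at = as.character(rec$occurred_at),
        line = i, stringsAsFactors = FALSE)
    } else {
      res[[length(res) + 1L]] <- data.frame(
        report_id = as.character(rec$report_id),
        patient_id = as.character(rec$patient_id),
        value = as.numeric(rec$value),
        collected_at = as.character(rec$collected_at),
        reported_at = as.character(rec$reported_at), stringsAsFactors = FALSE)
    }
  }
  patients <- if (length(pat)) unique(do.call(rbind, pat)) else NULL
  episodes <- if (length(epi)) do.call(rbind, epi) else NULL
  results  <- if (length(res)) do.call(rbind, res) else NULL
  if (length(disch)) {
    dd <- do.call(rbind, disch)
    for (j in seq_len(nrow(dd))) {
      k <- match(dd$episode_id[j], episodes$episode_id)
      if (is.na(k)) {
        input_error("line %d: DISCHARGE for unknown episode '%s' (field 'episode_id')",
                    dd$line[j], dd$episode_id[j])
      }
      if (!is.na(episodes$discharged_at[k])) {
        input_error("line %d: DISCHARGE for already-closed episode '%s' (field 'episode_id')",
                    dd$line[j], dd$episode_id[j])
      }
      episodes$discharged_at[k] <- dd$discharged_at[j]
    }
  }
  ehr_log(patients, episodes, results, nhs_check = nhs_check)
}

read_event_log_csv <- function(dir, nhs_check) {
  if (!dir.exists(dir)) {
    io_error("csv event log must be a directory containing admissions.csv, discharges.csv, hba1c.csv: %s",
             dir)
  }
  rd <- function(name, required) {
    p <- file.path(dir, name)
    if (!file.exists(p)) {
      if (required) io_error("missing %s in %s", name, dir) else return(NULL)
    }
    utils::read.csv(p, stringsAsFactors = FALSE, colClasses = "character")
  }
  adm <- rd("admissions.csv", required = TRUE)
  dis <- rd("discharges.csv", required = FALSE)
  hba <- rd("hba1c.csv", required = FALSE)
  need_cols(adm, c("episode_id", "patient_id", "ward_id", "nhs_number",
                   "full_name", "admitted_at"), "admissions.csv")
  patients <- unique(adm[, c("patient_id", "nhs_number", "full_name")])
  if (!is.null(adm$date_of_birth)) {
    patients$date_of_birth <- adm$date_of_birth[match(patients$patient_id, adm$patient_id)]
  }
  episodes <- adm[, c("episode_id", "patient_id", "ward_id", "admitted_at")]
  episodes$discharged_at <- NA_character_
  if (!is.null(dis) && nrow(dis)) {
    need_cols(dis, c("episode_id", "discharged_at"), "discharges.csv")
    k <- match(dis$episode_id, episodes$episode_id)
    if (anyNA(k)) {
      input_error("discharges.csv: DISCHARGE for unknown episode '%s' (field 'episode_id')",
                  dis$episode_id[which(is.na(k))[1L]])
    }
    episodes$discharged_at[k] <- dis$discharged_at
  }
  if (!is.null(hba) && nrow(hba)) {
    need_cols(hba, c("report_id", "patient_id", "value", "collected_at",
                     "reported_at"), "hba1c.csv")
  }
  ehr_log(patients, episodes, hba, nhs_check = nhs_check)
}

#' Write an event log to JSONL
#'
#' Inverse of [read_event_log()]: one event object per line in chronological
#' order, suitable for replay or archiving.
#'
#' @param log an [ehr_log()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "ehr_log"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  ev <- log$events
  for (i in seq_len(nrow(ev))) {
    kind <- ev$kind[i]; key <- ev$key[i]
    rec <- if (kind == "ADMISSION") {
      e <- log$episodes[log$episodes$episode_id == key, ]
      p <- log$patients[log$patients$patient_id == e$patient_id, ]
      list(kind = "ADMISSION", occurred_at = format_instant(e$admitted_at),
           episode_id = e$episode_id, patient_id = e$patient_id,
           ward_id = e$ward_id, nhs_number = p$nhs_number,
           full_name = p$full_name,
           date_of_birth = if (is.na(p$date_of_birth)) NULL else p$date_of_birth)
    } else if (kind == "DISCHARGE") {
      e <- log$episodes[log$episodes$episode_id == key, ]
      list(kind = "DISCHARGE", occurred_at = format_instant(e$discharged_at),
           episode_id = e$episode_id)
    } else {
      r <- log$results[log$results$report_id == key, ]
      list(kind = "HBA1C_REPORT", occurred_at = format_instant(r$reported_at),
           report_id = r$report_id, patient_id = r$patient_id, value = r$value,
           collected_at = format_instant(r$collected_at),
           reported_at = format_instant(r$reported_at))
    }
    rec <- rec[!vapply(rec, is.null, logical(1L))]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
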