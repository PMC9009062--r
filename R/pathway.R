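# The digitalised dysglycaemia/diabetes pathway: HbA1c band classification
# against configurable thresholds, IFCC<->DCCT unit conversion, red-flag
# determination, and per-band guideline recommendation assembly.
#
# Default thresholds follow NICE diagnostic cut-offs: HbA1c >= 42 mmol/mol is
# non-diabetic hyperglycaemia (pre-diabetes), >= 48 mmol/mol is diabetes, and
# >= 86 mmol/mol (~10% DCCT) is treated as severe dysglycaemia warranting
# urgent specialist referral.  All are configuration, never hard-coded.

#' Ordered glycaemic band codes
#'
#' The four bands, in increasing severity:
#' `NORMAL < PRE_DIABETES < DIABETES < SEVERE_DYSGLYCAEMIA`.
#' @export
GLYCAEMIC_BANDS <- c("NORMAL", "PRE_DIABETES", "DIABETES", "SEVERE_DYSGLYCAEMIA")

#' Band threshold set
#'
#' @param pre_diabetes_min lower edge of the pre-diabetes band, mmol/mol.
#' @param diabetes_min lower edge of the diabetes band, mmol/mol.
#' @param severe_min lower edge of the severe-dysglycaemia band, mmol/mol.
#' @param red_flag_min values at or above this are highlighted in red in
#'   rendered alerts; must equal `pre_diabetes_min` (any abnormal result
#'   shows red, the default) or `diabetes_min`.
#' @return a validated `band_thresholds` list.
#' @export
band_thresholds <- function(pre_diabetes_min = 42, diabetes_min = 48,
                            severe_min = 86, red_flag_min = pre_diabetes_min) {
  th <- list(pre_diabetes_min = as.numeric(pre_diabetes_min),
             diabetes_min = as.numeric(diabetes_min),
             severe_min = as.numeric(severe_min),
             red_flag_min = as.numeric(red_flag_min))
  if (!(th$pre_diabetes_min > 0 && th$pre_diabetes_min < th$diabetes_min &&
        th$diabetes_min < th$severe_min)) {
    config_error("thresholds must satisfy 0 < pre_diabetes_min < diabetes_min < severe_min")
  }
  if (!th$red_flag_min %in% c(th$pre_diabetes_min, th$diabetes_min)) {
    config_error("red_flag_min must equal pre_diabetes_min or diabetes_min")
  }
  structure(th, class = "band_thresholds")
}

#' Classify an HbA1c value into a glycaemic band
#'
#' Bands partition the sane value range with lower edges inclusive, matching
#' diagnostic convention (diabetes is diagnosed at HbA1c >= 48 mmol/mol):
#' `NORMAL` below `pre_diabetes_min`; `PRE_DIABETES` up to but excluding
#' `diabetes_min`; `DIABETES` up to but excluding `severe_min`;
#' `SEVERE_DYSGLYCAEMIA` at or above `severe_min`.
#'
#' @param value HbA1c in mmol/mol (IFCC); vectorised.
#' @param thresholds a [band_thresholds()] set.
#' @return character vector of band codes (see [GLYCAEMIC_BANDS]).
#' @export
classify_band <- function(value, thresholds = band_thresholds()) {
  value <- as.numeric(value)
  if (anyNA(value) || any(value <= 0 | value >= 200)) {
    input_error("HbA1c value outside sane bounds (0, 200) mmol/mol")
  }
  out <- character(length(value))
  out[value < thresholds$pre_diabetes_min] <- "NORMAL"
  out[value >= thresholds$pre_diabetes_min & value < thresholds$diabetes_min] <- "PRE_DIABETES"
  out[value >= thresholds$diabetes_min & value < thresholds$severe_min] <- "DIABETES"
  out[value >= thresholds$severe_min] <- "SEVERE_DYSGLYCAEMIA"
  out
}

#' Red-flag determination
#'
#' A result is red-flagged when it is raised at or above the configured
#' `red_flag_min` threshold (by default the pre-diabetes cut-off, so any
#' abnormal result is flagged).
#'
#' @inheritParams classify_band
#' @return logical vector.
#' @export
is_red_flag <- function(value, thresholds = band_thresholds()) {
  value <- as.numeric(value)
  if (anyNA(value) || any(value <= 0 | value >= 200)) {
    input_error("HbA1c value outside sane bounds (0, 200) mmol/mol")
  }
  value >= thresholds$red_flag_min
}

#' Convert HbA1c between IFCC (mmol/mol) and DCCT (%) units
#'
#' Uses the NGSP/IFCC master linear relationship
#' `percent = 0.09148 * mmol + 2.152`. `mmol_to_percent()` rounds to one
#' decimal for display; `percent_to_mmol()` is its exact inverse (round-trips
#' within 0.05 mmol/mol at display precision).
#'
#' @param value HbA1c value(s), mmol/mol or %, strictly positive.
#' @return converted value(s).
#' @export
mmol_to_percent <- function(value) {
  value <- as.numeric(value)
  if (anyNA(value) || any(value <= 0)) input_error("HbA1c mmol/mol value must be positive")
  round(value * 0.09148 + 2.152, 1L)
}

#' @rdname mmol_to_percent
#' @export
percent_to_mmol <- function(value) {
  value <- as.numeric(value)
  if (anyNA(value) || any(value <= 2.152)) input_error("HbA1c %% value out of range")
  (value - 2.152) / 0.09148
}

# ---------------------------------------------------------------------------
# Knowledge base / recommendations

.REC_CATEGORIES <- c("MONITORING", "LIFESTYLE", "SCREENING", "PHARMACOLOGICAL",
                     "REFERRAL", "LINKS")

#' Guideline recommendations for a glycaemic band
#'
#' Deterministic lookup into the knowledge base: the ordered item list for
#' the band, plus the known-diabetes intensification items when
#' `known_diabetes = TRUE`. The known-diabetes flag is an explicit input and
#' is never inferred from HbA1c values, since a well-controlled history is
#' not evident from the level itself.
#'
#' @param band a band code from [GLYCAEMIC_BANDS], or `"reminder"` for the
#'   monitoring-reminder item set.
#' @param known_diabetes logical; patient has a documented diabetes history.
#' @param kb knowledge base, as loaded by [load_pathway_config()]
#'   (`config$knowledge_base`).
#' @return data.frame with columns `category` and `text`, one row per item.
#' @export
recommendations_for <- function(band, known_diabetes = FALSE,
                                kb = default_pathway_config()$knowledge_base) {
  if (!band %in% c(GLYCAEMIC_BANDS, "reminder")) {
    lookup_error("unknown band '%s'", band)
  }
  items <- kb[[band]]
  if (is.null(items)) config_error("knowledge base missing entry for band '%s'", band)
  if (isTRUE(known_diabetes) && band %in% c("DIABETES", "SEVERE_DYSGLYCAEMIA") &&
      !is.null(kb$known_diabetes_extra)) {
    items <- c(items, kb$known_diabetes_extra)
  }
  data.frame(
    category = vapply(items, function(x) x$category, character(1L)),
    text = vapply(items, function(x) x$text, character(1L)),
    stringsAsFactors = FALSE
  )
}

validate_knowledge_base <- function(kb) {
  for (band in GLYCAEMIC_BANDS) {
    items <- kb[[band]]
    if (is.null(items) || length(items) == 0L) {
      config_error("knowledge base missing entry for band '%s'", band)
    }
    for (it in items) {
      if (is.null(it$category) || is.null(it$text) ||
          !it$category %in% .REC_CATEGORIES) {
        config_error("knowledge base band '%s': items need a category in {%s} and text",
                     band, paste(.REC_CATEGORIES, collapse = ", "))
      }
    }
  }
  if (is.null(kb$reminder) || length(kb$reminder) == 0L) {
    config_error("knowledge base missing 'reminder' item set")
  }
  sev <- vapply(kb$SEVERE_DYSGLYCAEMIA, function(x) x$category, character(1L))
  if (!"REFERRAL" %in% sev) {
    config_error("SEVERE_DYSGLYCAEMIA knowledge base entry must include a REFERRAL item")
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Pathway configuration document

#' Load and validate a pathway configuration
#'
#' The configuration document (YAML or JSON) bundles every tunable: band
#' thresholds, the red-flag threshold, the reminder policy (first reminder 4
#' days post-admission, weekly thereafter, surfaced at a daily evaluation
#' tick), the recommendation knowledge base, ward-to-clinician routing, and
#' display options. Validation happens here, at load time, so rule
#' evaluation never encounters a malformed knowledge base.
#'
#' @param path path to a YAML (or JSON) config; `NULL` loads the packaged
#'   default.
#' @return a validated `pathway_config` list with elements `thresholds`
#'   ([band_thresholds()]), `reminder_policy`, `knowledge_base`, `routing`,
#'   `history_limit`, `red_flag_marker`, `nhs_check`.
#' @export
load_pathway_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pathway-config.yaml", package = "glycalert")
  }
  if (!file.exists(path)) config_error("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  as_pathway_config(raw)
}

#' @rdname load_pathway_config
#' @export
default_pathway_config <- function() load_pathway_config(NULL)

as_pathway_config <- function(raw) {
  th <- raw$thresholds %||% list()
  thresholds <- band_thresholds(
    pre_diabetes_min = th$pre_diabetes_min %||% 42,
    diabetes_min = th$diabetes_min %||% 48,
    severe_min = th$severe_min %||% 86,
    red_flag_min = th$red_flag_min %||% th$pre_diabetes_min %||% 42)
  rp <- raw$reminder_policy %||% list()
  policy <- reminder_policy(
    first_reminder_after_days = rp$first_reminder_after_days %||% 4,
    reminder_interval_days = rp$reminder_interval_days %||% 7,
    evaluation_time_of_day = rp$evaluation_time_of_day %||% "09:00")
  kb <- raw$knowledge_base
  if (is.null(kb)) config_error("config missing knowledge_base")
  validate_knowledge_base(kb)
  routing <- raw$routing %||% list(wards = list())
  hist_limit <- as.integer(raw$history_limit %||% 10L)
  if (is.na(hist_limit) || hist_limit < 0L) config_error("history_limit must be >= 0")
  structure(
    list(thresholds = thresholds,
         reminder_policy = policy,
         knowledge_base = kb,
         routing = routing,
         history_limit = hist_limit,
         red_flag_marker = raw$red_flag_marker %||% "** RAISED **",
         nhs_check = raw$nhs_check %||% "warn"),
    class = "pathway_config"
  )
}

#' Reminder policy
#'
#' Untested inpatients get a first screening reminder
#' `first_reminder_after_days` after the admission instant (exact 24-hour
#' days) and further reminders every `reminder_interval_days`, each surfaced
#' at the next daily evaluation tick (`evaluation_time_of_day`, UTC).
#'
#' @param first_reminder_after_days days from admission to first reminder
#'   (default 4).
#' @param reminder_interval_days days between subsequent reminders
#'   (default 7).
#' @param evaluation_time_of_day `"HH:MM"` clock time of the daily
#'   evaluation tick (default `"09:00"`).
#' @return a `reminder_policy` list; durations stored in seconds.
#' @export
reminder_policy <- function(first_reminder_after_days = 4,
                            reminder_interval_days = 7,
                            evaluation_time_of_day = "09:00") {
  first <- as.numeric(first_reminder_after_days)
  interval <- as.numeric(reminder_interval_days)
  if (is.na(first) || first <= 0 || is.na(interval) || interval <= 0) {
    config_error("reminder policy durations must be positive")
  }
  structure(
    list(first_reminder_after = first * 86400,
         reminder_interval = interval * 86400,
         evaluation_tod = parse_clock_time(evaluation_time_of_day),
         evaluation_time_of_day = evaluation_time_of_day),
    class = "reminder_policy"
  )
}
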