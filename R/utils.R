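# Internal helpers: classed conditions and strict ISO-8601 instant handling.

glyc_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "glycalert_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

input_error     <- function(fmt, ...) glyc_stop("glycalert_input_error", fmt, ...)
config_error    <- function(fmt, ...) glyc_stop("glycalert_config_error", fmt, ...)
io_error        <- function(fmt, ...) glyc_stop("glycalert_io_error", fmt, ...)
integrity_error <- function(fmt, ...) glyc_stop("glycalert_integrity_error", fmt, ...)
lookup_error    <- function(fmt, ...) glyc_stop("glycalert_lookup_error", fmt, ...)

glyc_warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.INSTANT_RE <- "^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}(Z|[+-][0-9]{2}:?[0-9]{2})$"

#' Parse ISO-8601 instants with an explicit UTC offset
#'
#' Timestamps without an offset are rejected: reminder arithmetic over ward
#' stays must be unambiguous, so naive local times are treated as input
#' errors rather than guessed at.
#'
#' @param x character vector of timestamps, e.g. "2023-06-01T09:00:00+00:00".
#' @param field field name used in error messages.
#' @return `POSIXct` vector in UTC.
#' @keywords internal
parse_instant <- function(x, field = "timestamp") {
  if (length(x) == 0L) return(as.POSIXct(character(), tz = "UTC"))
  x <- as.character(x)
  bad <- is.na(x) | !grepl(.INSTANT_RE, x)
  if (any(bad)) {
    input_error("field '%s': not an ISO-8601 instant with explicit offset: %s",
                field, x[which(bad)[1L]])
  }
  norm <- sub("Z$", "+0000", x)
  norm <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", norm)
  out <- as.POSIXct(norm, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (anyNA(out)) {
    input_error("field '%s': unparseable instant: %s", field, x[which(is.na(out))[1L]])
  }
  out
}

#' @keywords internal
format_instant <- function(t) {
  if (length(t) == 0L) return(character())
  format(t, format = "%Y-%m-%dT%H:%M:%S+00:00", tz = "UTC")
}

# Parse "HH:MM" clock time into seconds past midnight.
parse_clock_time <- function(x) {
  if (!is.character(x) || length(x) != 1L || !grepl("^[0-9]{2}:[0-9]{2}$", x)) {
    config_error("evaluation_time_of_day must be 'HH:MM', got: %s",
                 paste(x, collapse = ","))
  }
  h <- as.integer(substr(x, 1, 2)); m <- as.integer(substr(x, 4, 5))
  if (h > 23L || m > 59L) config_error("invalid clock time: %s", x)
  h * 3600L + m * 60L
}

# Instant of the daily evaluation tick on the same UTC date as `t`.
tick_on_date <- function(date, tod_seconds) {
  as.POSIXct(as.numeric(as.POSIXct(paste0(format(date, "%Y-%m-%d"), "T00:00:00Z"),
                                   format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) +
               tod_seconds,
             tz = "UTC", origin = "1970-01-01")
}
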