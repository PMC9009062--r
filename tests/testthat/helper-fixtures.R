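# Shared fixture builders: instants anchored at a 09:00 admission so
# reminder due instants coincide with the daily evaluation tick.

day_at <- function(k, hh = 9, mm = 0, ss = 0) {
  as.POSIXct("2023-06-01 00:00:00", tz = "UTC") + k * 86400 +
    hh * 3600 + mm * 60 + ss
}

fx_patient <- function(i, nhs = NULL) {
  data.frame(patient_id = sprintf("P%02d", i),
             nhs_number = nhs %||% c("9434765919", "9434765870", "9434765889",
                                     "9434765897", "9434765900")[i],
             full_name = sprintf("Test Patient %02d", i),
             stringsAsFactors = FALSE)
}

fx_episode <- function(i, adm, dis = NA, ward = "WARD_X") {
  data.frame(episode_id = sprintf("E%02d", i), patient_id = sprintf("P%02d", i),
             ward_id = ward, admitted_at = adm,
             discharged_at = if (length(dis) == 1L && is.na(dis[1L]))
               as.POSIXct(NA_real_, tz = "UTC", origin = "1970-01-01") else dis,
             stringsAsFactors = FALSE)
}

fx_result <- function(i, k, value, reported, collected = reported - 3600) {
  data.frame(report_id = sprintf("R%02d-%d", i, k),
             patient_id = sprintf("P%02d", i), value = value,
             collected_at = collected, reported_at = reported,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the worked three-patient, twenty-day ward log:
#   A (P01) admitted day 0, HbA1c 50 reported day 1
#   B (P02) admitted day 0, discharged day 9, never tested
#   C (P03) admitted day 0, never tested through day 20
fx_worked_log <- function() {
  ehr_log(
    rbind(fx_patient(1), fx_patient(2), fx_patient(3)),
    rbind(fx_episode(1, day_at(0)), fx_episode(2, day_at(0), day_at(9)),
          fx_episode(3, day_at(0))),
    fx_result(1, 1, 50, day_at(1, 10)))
}
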