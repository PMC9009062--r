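# Seeded synthetic ward-cohort generator, plus hand-built deterministic
# scenario fixtures that each isolate one alerting rule.
#
# The generator emulates what the rules engine consumes and nothing more:
# ward occupancy under a bed cap, admission/length-of-stay processes, HbA1c
# ordering delays, and a glycaemic value mixture echoing the prevalence
# reported for psychosis populations in South London (20% diabetes, a
# further 30% dysglycaemia). It does not model diagnoses or drug effects.

#' Synthetic cohort parameters
#'
#' Defaults describe a one-month, three-ward acute psychiatric unit with
#' 18/19/23 beds: mean length of stay 21 days (geometric, memoryless), 85%
#' occupancy pressure, HbA1c ordered for 60% of admissions with a uniform
#' 0-6 day ordering delay, and a band mixture of 50% normal, 30%
#' pre-diabetes-range, 15% diabetes-range and 5% severe (the diabetes
#' prevalence split between controlled and decompensated values).
#'
#' @param wards named integer vector of bed counts per ward.
#' @param horizon_days length of the simulated window, days.
#' @param mean_length_of_stay_days mean stay, days (geometric).
#' @param occupancy_target fraction of beds occupied, in (0, 1].
#' @param p_test_within probability an admission has an HbA1c ordered.
#' @param test_delay_max_days ordering delay is uniform on [0, this].
#' @param value_mixture named proportions over
#'   normal/pre_diabetes/diabetes/severe, summing to 1.
#' @param prior_history_rate fraction of patients carrying 1-3 pre-admission
#'   historical results.
#' @param start ISO-8601 instant of day 0.
#' @param seed integer RNG seed; the generator is pure in (params, seed).
#' @return a validated `cohort_params` list.
#' @export
cohort_params <- function(wards = c(WARD_X = 18L, WARD_Y = 19L, WARD_Z = 23L),
                          horizon_days = 30L,
                          mean_length_of_stay_days = 21,
                          occupancy_target = 0.85,
                          p_test_within = 0.6,
                          test_delay_max_days = 6,
                          value_mixture = c(normal = 0.50, pre_diabetes = 0.30,
                                            diabetes = 0.15, severe = 0.05),
                          prior_history_rate = 0.3,
                          start = "2023-06-01T00:00:00+00:00",
                          seed = 1L) {
  if (is.null(names(wards)) || any(!nzchar(names(wards)))) {
    config_error("wards must be a named vector of bed counts")
  }
  if (any(wards <= 0)) config_error("bed_count must be > 0")
  if (horizon_days < 0) config_error("horizon_days must be >= 0")
  if (mean_length_of_stay_days <= 0) config_error("mean length of stay must be positive")
  if (occupancy_target <= 0 || occupancy_target > 1) {
    config_error("occupancy_target must be in (0, 1] (a zero target over a non-empty horizon is infeasible)")
  }
  probs <- c(p_test_within, prior_history_rate)
  if (any(probs < 0 | probs > 1)) config_error("probabilities must lie in [0, 1]")
  mix_names <- c("normal", "pre_diabetes", "diabetes", "severe")
  if (!setequal(names(value_mixture), mix_names)) {
    config_error("value_mixture needs proportions named %s", paste(mix_names, collapse = ", "))
  }
  value_mixture <- value_mixture[mix_names]
  if (abs(sum(value_mixture) - 1) > 1e-9 || any(value_mixture < 0)) {
    config_error("value_mixture proportions must be non-negative and sum to 1")
  }
  structure(
    list(wards = wards, horizon_days = as.integer(horizon_days),
         mean_length_of_stay_days = mean_length_of_stay_days,
         occupancy_target = occupancy_target,
         p_test_within = p_test_within,
         test_delay_max_days = test_delay_max_days,
         value_mixture = value_mixture,
         prior_history_rate = prior_history_rate,
         start = parse_instant(start, "start"),
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

# Per-band value distributions: truncated normals inside the band bounds
# (the default 42/48/86 banding).
.BAND_DISTS <- list(
  normal       = list(mean = 36,   sd = 4,   lo = 25, hi = 41.9),
  pre_diabetes = list(mean = 44.5, sd = 1.7, lo = 42, hi = 47.9),
  diabetes     = list(mean = 60,   sd = 10,  lo = 48, hi = 85.9),
  severe       = list(mean = 95,   sd = 8,   lo = 86, hi = 130)
)

rtruncnorm1 <- function(mean, sd, lo, hi) {
  # inverse-CDF sampling keeps one RNG draw per value (determinism is easier
  # to reason about than rejection loops)
  u <- stats::runif(1L, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

random_nhs_numbers <- function(n) {
  out <- character(0L)
  while (length(out) < n) {
    d9 <- sample(0:9, 9L, replace = TRUE)
    chk <- nhs_check_digit(d9)
    if (is.na(chk)) next
    cand <- paste0(paste(d9, collapse = ""), chk)
    if (!cand %in% out) out <- c(out, cand)
  }
  out
}

#' Generate a synthetic ward event log
#'
#' Day-by-day simulation per ward: beds vacated by discharge are refilled by
#' a Poisson admission stream calibrated to the occupancy target (day 0
#' starts at the target census), each admission draws a geometric length of
#' stay, a glycaemic state from the value mixture, and, with probability
#' `p_test_within`, an HbA1c collection after a uniform ordering delay with
#' a lab turnaround of 2-24 hours. A fraction of patients carry 1-3
#' pre-admission historical results. The daily census never exceeds the bed
#' count, and the same parameters and seed always reproduce the same log.
#'
#' @param params a [cohort_params()].
#' @return an [ehr_log()].
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  if (params$horizon_days == 0L) return(ehr_log())

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  start <- params$start
  H <- params$horizon_days
  mean_los <- params$mean_length_of_stay_days
  pat <- list(); epi <- list(); res <- list()
  counter <- 0L
  n_guess <- sum(params$wards) * 3L
  nhs_pool <- random_nhs_numbers(n_guess)

  for (w in names(params$wards)) {
    beds <- params$wards[[w]]
    free_day <- integer(0L)    # day index at which each occupied bed frees
    lambda <- beds * params$occupancy_target / mean_los
    for (d in 0:(H - 1L)) {
      free_day <- free_day[free_day > d]
      vacancies <- beds - length(free_day)
      n_admit <- if (d == 0L) min(vacancies, round(beds * params$occupancy_target))
                 else min(vacancies, stats::rpois(1L, lambda))
      if (n_admit <= 0L) next
      for (j in seq_len(n_admit)) {
        counter <- counter + 1L
        if (counter > length(nhs_pool)) {
          nhs_pool <- c(nhs_pool, random_nhs_numbers(n_guess))
        }
        pid <- sprintf("P%04d", counter)
        # whole seconds only: the JSONL format is second-resolution
        admitted <- start + d * 86400 + floor(stats::runif(1L, 8 * 3600, 20 * 3600))
        los <- stats::rgeom(1L, 1 / mean_los) + 1L
        # the bed stays blocked through the whole discharge day, so two
        # stays never overlap even intraday
        free_day <- c(free_day, d + los + 1L)
        discharged <- if (d + los >= H) {
          as.POSIXct(NA_real_, tz = "UTC", origin = "1970-01-01")
        } else admitted + los * 86400
        pat[[counter]] <- data.frame(
          patient_id = pid, nhs_number = nhs_pool[counter],
          full_name = sprintf("Synthetic Patient %04d", counter),
          date_of_birth = NA_character_, stringsAsFactors = FALSE)
        epi[[counter]] <- data.frame(
          episode_id = sprintf("E%04d", counter), patient_id = pid,
          ward_id = w, admitted_at = admitted, discharged_at = discharged,
          stringsAsFactors = FALSE)

        state <- sample(names(params$value_mixture), 1L,
                        prob = params$value_mixture)
        dist <- .BAND_DISTS[[state]]

        if (stats::runif(1L) < params$p_test_within) {
          delay <- floor(stats::runif(1L, 0, params$test_delay_max_days * 86400))
          collected <- admitted + delay
          reported <- collected + floor(stats::runif(1L, 2 * 3600, 24 * 3600))
          res[[length(res) + 1L]] <- data.frame(
            report_id = sprintf("R%s-0", pid), patient_id = pid,
            value = round(rtruncnorm1(dist$mean, dist$sd, dist$lo, dist$hi), 1L),
            collected_at = collected, reported_at = reported,
            stringsAsFactors = FALSE)
        }
        if (stats::runif(1L) < params$prior_history_rate) {
          n_hist <- sample(1:3, 1L)
          for (k in seq_len(n_hist)) {
            reported <- admitted - floor(stats::runif(1L, 30, 365) * 86400)
            res[[length(res) + 1L]] <- data.frame(
              report_id = sprintf("R%s-h%d", pid, k), patient_id = pid,
              value = round(rtruncnorm1(dist$mean, dist$sd, dist$lo, dist$hi), 1L),
              collected_at = reported - 6 * 3600, reported_at = reported,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  ehr_log(do.call(rbind, pat), do.call(rbind, epi),
          if (length(res)) do.call(rbind, res) else NULL)
}

#' Horizon instant of a synthetic cohort
#'
#' End of the simulated window: `start + horizon_days` days.
#' @param params a [cohort_params()].
#' @return `POSIXct`.
#' @export
cohort_horizon <- function(params) params$start + params$horizon_days * 86400

# ---------------------------------------------------------------------------
# Deterministic scenario fixtures, one per validation standard.

.SCENARIO_NAMES <- c("S1_new_result", "S2_day4_reminder", "S3_weekly_reminders",
                     "S4_history_summary", "S5_banding", "S6_red_flag",
                     "S7_identity", "S8_no_leakage", "S9_no_spurious",
                     "S10_discharge_suppression")

#' Hand-built validation scenario fixtures
#'
#' Each scenario is a small deterministic event log isolating one alerting
#' rule, paired with the exact expected alert multiset (hand-computed, and
#' cross-checked against the brute-force oracle in the test suite).
#'
#' @param name one of `S1_new_result`, `S2_day4_reminder`,
#'   `S3_weekly_reminders`, `S4_history_summary`, `S5_banding`,
#'   `S6_red_flag`, `S7_identity`, `S8_no_leakage`, `S9_no_spurious`,
#'   `S10_discharge_suppression`.
#' @return list with `log` (an [ehr_log()]), `horizon` (`POSIXct`), and
#'   `expected`: a data.frame of expected alerts with columns `type`,
#'   `patient_id`, `episode_id`, `triggered_at`, `band`, `red_flag`,
#'   `n_history`.
#' @export
scenario <- function(name) {
  if (!name %in% .SCENARIO_NAMES) {
    lookup_error("unknown scenario '%s'; available: %s", name,
                 paste(.SCENARIO_NAMES, collapse = ", "))
  }
  # day-k instants anchored at an 09:00 admission so reminder due instants
  # coincide with evaluation ticks
  day <- function(k, hh = 9, mm = 0) {
    parse_instant("2023-06-01T00:00:00+00:00") + k * 86400 + hh * 3600 + mm * 60
  }
  p <- function(i) data.frame(
    patient_id = sprintf("SP%02d", i),
    nhs_number = c("9434765919", "9434765870", "9434765889", "9434765897",
                   "9434765900")[i],  # all pass the mod-11 check
    full_name = sprintf("Scenario Patient %02d", i),
    stringsAsFactors = FALSE)
  e <- function(i, adm, dis = NA, ward = "WARD_X") data.frame(
    episode_id = sprintf("SE%02d", i), patient_id = sprintf("SP%02d", i),
    ward_id = ward, admitted_at = adm,
    discharged_at = if (length(dis) == 1L && is.na(dis[1L]))
      as.POSIXct(NA_real_, tz = "UTC", origin = "1970-01-01") else dis,
    stringsAsFactors = FALSE)
  r <- function(i, k, value, reported, collected = reported - 3600) data.frame(
    report_id = sprintf("SR%02d-%d", i, k), patient_id = sprintf("SP%02d", i),
    value = value, collected_at = collected, reported_at = reported,
    stringsAsFactors = FALSE)
  exp_row <- function(type, i, triggered, band = NA_character_,
                      red = FALSE, n_history = 0L) data.frame(
    type = type, patient_id = sprintf("SP%02d", i),
    episode_id = sprintf("SE%02d", i), triggered_at = triggered,
    band = band, red_flag = red, n_history = as.integer(n_history),
    stringsAsFactors = FALSE)

  sc <- switch(name,
    S1_new_result = list(
      log = ehr_log(p(1), e(1, day(0)), r(1, 1, 50, day(1, 10))),
      horizon = day(3),
      expected = exp_row("NEW_RESULT", 1, day(1, 10), "DIABETES", TRUE)),
    S2_day4_reminder = list(
      log = ehr_log(p(1), e(1, day(0))),
      horizon = day(6),
      expected = exp_row("MONITORING_REMINDER", 1, day(4))),
    S3_weekly_reminders = list(
      log = ehr_log(p(1), e(1, day(0), day(20))),
      horizon = day(21),
      expected = rbind(exp_row("MONITORING_REMINDER", 1, day(4)),
                       exp_row("MONITORING_REMINDER", 1, day(11)),
                       exp_row("MONITORING_REMINDER", 1, day(18)))),
    S4_history_summary = list(
      log = ehr_log(p(1), e(1, day(0)),
                    rbind(r(1, 1, 40, day(-200)), r(1, 2, 43, day(-100)),
                          r(1, 3, 50, day(1, 10)))),
      horizon = day(3),
      expected = exp_row("NEW_RESULT", 1, day(1, 10), "DIABETES", TRUE,
                         n_history = 2L)),
    S5_banding = list(
      log = ehr_log(do.call(rbind, lapply(1:4, p)),
                    do.call(rbind, lapply(1:4, e, adm = day(0))),
                    rbind(r(1, 1, 30, day(1, 10)), r(2, 1, 42, day(1, 11)),
                          r(3, 1, 48, day(1, 12)), r(4, 1, 86, day(1, 13)))),
      horizon = day(2),
      expected = rbind(
        exp_row("NEW_RESULT", 1, day(1, 10), "NORMAL", FALSE),
        exp_row("NEW_RESULT", 2, day(1, 11), "PRE_DIABETES", TRUE),
        exp_row("NEW_RESULT", 3, day(1, 12), "DIABETES", TRUE),
        exp_row("NEW_RESULT", 4, day(1, 13), "SEVERE_DYSGLYCAEMIA", TRUE))),
    S6_red_flag = list(
      log = ehr_log(rbind(p(1), p(2)),
                    rbind(e(1, day(0)), e(2, day(0))),
                    rbind(r(1, 1, 41, day(1, 10)), r(2, 1, 44, day(1, 11)))),
      horizon = day(2),
      expected = rbind(
        exp_row("NEW_RESULT", 1, day(1, 10), "NORMAL", FALSE),
        exp_row("NEW_RESULT", 2, day(1, 11), "PRE_DIABETES", TRUE))),
    S7_identity = ,
    S8_no_leakage = list(
      log = ehr_log(do.call(rbind, lapply(1:3, p)),
                    do.call(rbind, lapply(1:3, e, adm = day(0))),
                    rbind(r(1, 1, 35, day(1, 10)), r(2, 1, 52, day(1, 11)),
                          r(3, 1, 90, day(1, 12)))),
      horizon = day(2),
      expected = rbind(
        exp_row("NEW_RESULT", 1, day(1, 10), "NORMAL", FALSE),
        exp_row("NEW_RESULT", 2, day(1, 11), "DIABETES", TRUE),
        exp_row("NEW_RESULT", 3, day(1, 12), "SEVERE_DYSGLYCAEMIA", TRUE))),
    S9_no_spurious = list(
      log = ehr_log(do.call(rbind, lapply(1:4, p)),
                    rbind(e(1, day(0)), e(2, day(0), day(3)), e(3, day(0)),
                          e(4, day(0))),
                    rbind(r(1, 1, 50, day(1, 10)),
                          r(3, 1, 45, day(2, 10)), r(3, 2, 52, day(5, 10)),
                          r(4, 1, 44, day(-10)))),
      horizon = day(12, 9, 30),
      expected = rbind(
        exp_row("NEW_RESULT", 1, day(1, 10), "DIABETES", TRUE),
        exp_row("NEW_RESULT", 3, day(2, 10), "PRE_DIABETES", TRUE),
        exp_row("NEW_RESULT", 3, day(5, 10), "DIABETES", TRUE, n_history = 1L),
        exp_row("MONITORING_REMINDER", 4, day(4), n_history = 1L),
        exp_row("MONITORING_REMINDER", 4, day(11), n_history = 1L))),
    S10_discharge_suppression = list(
      log = ehr_log(rbind(p(1), p(2)),
                    rbind(e(1, day(0), day(2, 15)), e(2, day(0), day(9, 8))),
                    r(1, 1, 55, day(3, 10))),
      horizon = day(15),
      expected = exp_row("MONITORING_REMINDER", 2, day(4)))
  )
  sc$name <- name
  sc
}

#' @rdname scenario
#' @export
scenario_names <- function() .SCENARIO_NAMES
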