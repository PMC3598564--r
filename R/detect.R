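#' Detect concurrent-exposure PDDI episodes
#'
#' Batch equivalent of the nightly claims scan: for every rule and patient,
#' finds maximal episodes of concurrent exposure to a drug from `set_a` and
#' a drug from `set_b`, and emits exactly one event per episode. Two
#' non-reversed claims are concurrently active when their half-open supply
#' windows `[fill, fill + days_supply)` overlap (within `grace` days). The
#' chronologically later fill of the episode's initiating claim pair is the
#' "second" interacting drug: its fill date is the event's index date and
#' its prescriber is the alert addressee. For same-day fills the claim from
#' `set_b` is taken as second (ties broken by claim id) — an arbitrary but
#' documented convention, since a temporal order need not exist in the data.
#'
#' A new episode (and hence a possible re-alert) begins only when
#' concurrent exposure lapses for more than `grace` days and then recurs;
#' re-scanning an unchanged episode can never produce a second event.
#'
#' @param data A `claims_data` object (or a bare claims tibble).
#' @param bank A `ddi_rulebank`.
#' @param scan_window Optional date vector `c(start, end)`; only events
#'   with index date inside the closed window are kept.
#' @param grace Days of lapsed exposure tolerated within one episode
#'   (default 0).
#' @param incident_only If `TRUE`, keep only events whose second claim is
#'   the patient's first-ever fill of that drug (incident second fills).
#' @return Tibble of events ordered by (index_date, patient_id, rule_id):
#'   `event_id`, `rule_id`, `patient_id`, `first_claim_id`,
#'   `second_claim_id`, `first_drug_id`, `second_drug_id`, `index_date`,
#'   `alert_prescriber`, `lob`, `plan`, `episode_start`, `episode_end`.
#' @export
detect_events <- function(data, bank, scan_window = NULL, grace = 0,
                          incident_only = FALSE) {
  claims <- if (inherits(data, "claims_data")) data$claims else data
  patients <- if (inherits(data, "claims_data")) data$patients else NULL
  live <- active_supply_window(dplyr::filter(claims, !.data$reversed))
  events <- purrr::map(bank$rules, function(rule) {
    detect_rule_events(live, rule, grace)
  }) %>% dplyr::bind_rows()
  if (nrow(events) == 0L) {
    return(empty_events(patients))
  }
  if (incident_only) {
    first_fill <- live %>%
      dplyr::group_by(.data$patient_id, .data$drug_id) %>%
      dplyr::summarise(first_fill = min(.data$fill_date), .groups = "drop")
    events <- events %>%
      dplyr::left_join(first_fill,
                       by = c(patient_id = "patient_id",
                              second_drug_id = "drug_id")) %>%
      dplyr::filter(.data$index_date == .data$first_fill) %>%
      dplyr::select(-"first_fill")
    if (nrow(events) == 0L) return(empty_events(patients))
  }
  if (!is.null(scan_window)) {
    events <- dplyr::filter(events,
                            .data$index_date >= scan_window[1],
                            .data$index_date <= scan_window[2])
    if (nrow(events) == 0L) return(empty_events(patients))
  }
  if (!is.null(patients)) {
    events <- dplyr::left_join(
      events, dplyr::select(patients, "patient_id", "plan"), by = "patient_id")
  } else {
    events$plan <- "A"
  }
  events %>%
    dplyr::arrange(.data$index_date, .data$patient_id, .data$rule_id) %>%
    dplyr::mutate(event_id = sprintf("E%06d", dplyr::row_number()), .before = 1L)
}

detect_rule_events <- function(live, rule, grace) {
  a <- dplyr::filter(live, .data$drug_id %in% rule$set_a)
  b <- dplyr::filter(live, .data$drug_id %in% rule$set_b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(NULL)
  pairs <- dplyr::inner_join(
    dplyr::select(a, "patient_id", a_claim = "claim_id", a_drug = "drug_id",
                  a_fill = "fill_date", a_start = "window_start",
                  a_end = "window_end", a_rx = "prescriber_id", a_lob = "lob"),
    dplyr::select(b, "patient_id", b_claim = "claim_id", b_drug = "drug_id",
                  b_fill = "fill_date", b_start = "window_start",
                  b_end = "window_end", b_rx = "prescriber_id"),
    by = "patient_id", relationship = "many-to-many") %>%
    dplyr::filter(.data$a_start < .data$b_end + grace,
                  .data$b_start < .data$a_end + grace)
  if (nrow(pairs) == 0L) return(NULL)
  pairs <- pairs %>%
    dplyr::mutate(
      co_start = pmax(.data$a_start, .data$b_start),
      co_end = pmin(.data$a_end, .data$b_end),
      b_second = .data$b_fill >= .data$a_fill,  # same-day fills: set_b is second
      first_claim_id = dplyr::if_else(.data$b_second, .data$a_claim, .data$b_claim),
      second_claim_id = dplyr::if_else(.data$b_second, .data$b_claim, .data$a_claim),
      first_drug_id = dplyr::if_else(.data$b_second, .data$a_drug, .data$b_drug),
      second_drug_id = dplyr::if_else(.data$b_second, .data$b_drug, .data$a_drug),
      index_date = dplyr::if_else(.data$b_second, .data$b_fill, .data$a_fill),
      alert_prescriber = dplyr::if_else(.data$b_second, .data$b_rx, .data$a_rx)
    ) %>%
    dplyr::arrange(.data$patient_id, .data$co_start, .data$second_claim_id,
                   .data$first_claim_id)
  # merge overlapping/adjacent co-exposure intervals into maximal episodes
  pairs %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::mutate(
      running_end = cummax(as.numeric(.data$co_end)),
      new_episode = dplyr::row_number() == 1L |
        as.numeric(.data$co_start) > dplyr::lag(.data$running_end, default = -Inf) + grace,
      episode = cumsum(.data$new_episode)
    ) %>%
    dplyr::group_by(.data$patient_id, .data$episode) %>%
    dplyr::summarise(
      rule_id = rule$rule_id,
      first_claim_id = .data$first_claim_id[1L],
      second_claim_id = .data$second_claim_id[1L],
      first_drug_id = .data$first_drug_id[1L],
      second_drug_id = .data$second_drug_id[1L],
      index_date = .data$index_date[1L],
      alert_prescriber = .data$alert_prescriber[1L],
      lob = .data$a_lob[1L],
      episode_start = min(.data$co_start),
      episode_end = as.Date(max(as.integer(.data$co_end)), origin = "1970-01-01"),
      .groups = "drop") %>%
    dplyr::select(-"episode")
}

empty_events <- function(patients = NULL) {
  tibble::tibble(event_id = character(), rule_id = character(),
                 patient_id = character(), first_claim_id = character(),
                 second_claim_id = character(), first_drug_id = character(),
                 second_drug_id = character(), index_date = as.Date(character()),
                 alert_prescriber = character(), lob = character(),
                 plan = character(),
                 episode_start = as.Date(character()),
                 episode_end = as.Date(character()))
}

#' Apply alert policy to detected events
#'
#' Flags each detected event with whether a fax alert is generated:
#' alerts go out for events in alert-enabled plans, except rule /
#' line-of-business combinations the plan excluded (the managed Medicaid
#' plan suppressed benzodiazepine-azole alerts). Education-only rules do
#' generate alerts (to raise awareness) but are flagged non-evaluable.
#' One alert per (patient, rule, episode); a prescriber receives one alert
#' per alerted event, so prescribing the same interacting pair to several
#' patients yields several alerts.
#'
#' @param events Output of [detect_events()].
#' @param bank A `ddi_rulebank`.
#' @param alert_plans Plan codes whose events trigger alerts (default `"A"`).
#' @return `events` with logical columns `alerted` and `evaluable` and
#'   column `severity` appended.
#' @export
build_alerts <- function(events, bank, alert_plans = "A") {
  meta <- tibble::tibble(
    rule_id = vapply(bank$rules, `[[`, "", "rule_id"),
    evaluable = vapply(bank$rules, `[[`, NA, "evaluable"),
    severity = vapply(bank$rules, `[[`, "", "severity"),
    plan_exclusions = lapply(bank$rules, `[[`, "plan_exclusions")
  )
  events %>%
    dplyr::left_join(meta, by = "rule_id") %>%
    dplyr::mutate(
      excluded = purrr::map2_lgl(.data$lob, .data$plan_exclusions,
                                 function(l, ex) l %in% ex),
      alerted = .data$plan %in% alert_plans & !.data$excluded
    ) %>%
    dplyr::select(-"plan_exclusions", -"excluded")
}

#' Count alerts by rule or by prescriber
#'
#' @param events Alert-flagged events ([build_alerts()] output).
#' @param by `"rule"` or `"prescriber"`.
#' @return Tibble of alert counts, descending.
#' @export
alert_counts <- function(events, by = c("rule", "prescriber")) {
  by <- match.arg(by)
  key <- if (by == "rule") "rule_id" else "alert_prescriber"
  events %>%
    dplyr::filter(.data$alerted) %>%
    dplyr::count(.data[[key]], name = "n_alerts", sort = TRUE)
}

#' Keep events with at least `horizon` days of eligibility after the index
#'
#' Mirrors the programme's restriction to alerts whose patient had at
#' least 90 days of prescription-plan eligibility after the alert, so the
#' outcome window is fully observable. Boundary: eligibility ending exactly
#' `index + horizon` is retained.
#'
#' @param events Events tibble.
#' @param patients Patients tibble (for `eligibility_end`).
#' @param horizon Days (default 90).
#' @return Filtered events.
#' @export
eligibility_filter <- function(events, patients, horizon = 90) {
  events %>%
    dplyr::left_join(dplyr::select(patients, "patient_id", "eligibility_end"),
                     by = "patient_id") %>%
    dplyr::filter(.data$eligibility_end >= .data$index_date + horizon) %>%
    dplyr::select(-"eligibility_end")
}
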