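#' Ascertain 90-day successful therapy changes for matched events
#'
#' A "successful change" is the initiation — a dispensing claim — of a
#' recommended therapeutic alternative within 90 days of the event's index
#' date. Alternatives are specified a priori by the rulebank and keyed by
#' the interacting drugs actually involved in the event. Both arms are
#' ascertained against their own index dates. The window is exclusive at
#' the index day (day 0, the index fill itself, does not count) and
#' inclusive at day `window`: a qualifying fill at `index + 90` counts, at
#' `index + 91` does not. Reversed claims never qualify, and a fill of
#' either interacting drug itself never counts as a change.
#'
#' @param pairs Matched pairs from [match_cohorts()].
#' @param events The event table the pairs reference (for involved drugs).
#' @param claims Full claims history (tibble or `claims_data`).
#' @param bank A `ddi_rulebank`.
#' @param window Outcome window length in days (default 90).
#' @param index_offset Days added to the index date before the window
#'   opens (default 0; set to 1 to anchor on the morning-after fax send).
#' @param strict_switch If `TRUE`, additionally require that the involved
#'   interacting drugs are not refilled inside the window after the change
#'   fill (a stricter "switch" reading; off by default, which is the
#'   literal initiation definition).
#' @param incident_alternative If `TRUE`, only count alternatives absent
#'   from the patient's prior 180-day history ("new to the patient").
#' @return Tibble of outcome records, one per matched event and arm:
#'   `pair_id`, `rule_id`, `arm`, `event_id`, `patient_id`, `index_date`,
#'   `success`, `change_drug_id`, `days_to_change`.
#' @export
ascertain_changes <- function(pairs, events, claims, bank, window = 90,
                              index_offset = 0, strict_switch = FALSE,
                              incident_alternative = FALSE) {
  claims <- if (inherits(claims, "claims_data")) claims$claims else claims
  live <- dplyr::filter(claims, !.data$reversed)
  ev_cols <- dplyr::select(events, "event_id", "first_drug_id", "second_drug_id")
  long <- dplyr::bind_rows(
    pairs %>%
      dplyr::transmute(.data$pair_id, .data$rule_id, arm = "intervention",
                       event_id = .data$intervention_event_id,
                       patient_id = .data$intervention_patient_id,
                       index_date = .data$intervention_index),
    pairs %>%
      dplyr::transmute(.data$pair_id, .data$rule_id, arm = "control",
                       event_id = .data$control_event_id,
                       patient_id = .data$control_patient_id,
                       index_date = .data$control_index)
  ) %>%
    dplyr::left_join(ev_cols, by = "event_id") %>%
    dplyr::mutate(index_date = .data$index_date + index_offset)

  bad_rules <- setdiff(unique(long$rule_id), names(bank$rules))
  if (length(bad_rules)) {
    abort(sprintf("unknown rule id(s): %s", paste(bad_rules, collapse = ", ")),
          class = "pddialert_data_error")
  }
  non_eval <- unique(long$rule_id)[!vapply(bank$rules[unique(long$rule_id)],
                                           `[[`, NA, "evaluable")]
  if (length(non_eval)) {
    abort(sprintf("education-only rule(s) have no evaluable outcome: %s",
                  paste(non_eval, collapse = ", ")),
          class = "pddialert_data_error")
  }

  claims_by_patient <- split(live, live$patient_id)
  no_hist <- live[0L, , drop = FALSE]
  out <- purrr::pmap(long, function(pair_id, rule_id, arm, event_id, patient_id,
                                    index_date, first_drug_id, second_drug_id) {
    rule <- bank$rules[[rule_id]]
    involved <- c(first_drug_id, second_drug_id)
    alts <- setdiff(rule_alternatives(rule, involved), involved)
    hist <- claims_by_patient[[patient_id]] %||% no_hist
    qual <- hist[hist$drug_id %in% alts &
                   hist$fill_date > index_date &
                   hist$fill_date <= index_date + window, , drop = FALSE]
    if (incident_alternative && nrow(qual)) {
      prior <- hist[hist$fill_date >= index_date - 180 &
                      hist$fill_date <= index_date, , drop = FALSE]
      qual <- qual[!qual$drug_id %in% prior$drug_id, , drop = FALSE]
    }
    if (strict_switch && nrow(qual)) {
      first_change <- min(qual$fill_date)
      refilled <- any(hist$drug_id %in% involved &
                        hist$fill_date > first_change &
                        hist$fill_date <= index_date + window)
      if (refilled) qual <- qual[0L, , drop = FALSE]
    }
    if (nrow(qual) == 0L) {
      tibble::tibble(success = FALSE, change_drug_id = NA_character_,
                     days_to_change = NA_integer_)
    } else {
      qual <- qual[order(qual$fill_date, qual$claim_id), , drop = FALSE]
      tibble::tibble(success = TRUE, change_drug_id = qual$drug_id[1L],
                     days_to_change = as.integer(qual$fill_date[1L] - index_date))
    }
  })
  dplyr::bind_cols(
    dplyr::select(long, -"first_drug_id", -"second_drug_id"),
    dplyr::bind_rows(out))
}

#' Breakdown of chosen alternative drugs
#'
#' Counts, per rule (and optionally per arm), which recommended alternative
#' the changed patients actually initiated. Counts sum to the per-rule
#' success totals by construction.
#'
#' @param records Outcome records from [ascertain_changes()].
#' @param by_arm Also split by arm? Default `FALSE`.
#' @return Tibble `rule_id` (, `arm`), `change_drug_id`, `n`, descending
#'   within rule.
#' @export
change_breakdown <- function(records, by_arm = FALSE) {
  keys <- c("rule_id", if (by_arm) "arm", "change_drug_id")
  records %>%
    dplyr::filter(.data$success) %>%
    dplyr::count(dplyr::across(dplyr::all_of(keys)), name = "n") %>%
    dplyr::arrange(.data$rule_id, dplyr::desc(.data$n), .data$change_drug_id)
}
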