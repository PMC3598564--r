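#' Construct the 1:1 matched control cohorts
#'
#' For each rule, pairs every alerted (intervention) event with at most one
#' control event drawn from the non-alerted pool, under the matching
#' constraints: same rule, same gender, same line of business, index dates
#' in the same time period, and age at index within `age_tol` years. A
#' control patient can be used at most once across the whole study — even
#' if they have several PDDIs — while an intervention patient may appear in
#' several rule cohorts. Controls anchor on their own detection date (no
#' alert exists for them).
#'
#' The matcher is greedy nearest-age-first and fully deterministic: rules
#' are processed in descending intervention-event count, intervention
#' events within a stratum in patient-id order, and among equally-aged
#' candidates the lexicographically smallest control patient id wins.
#'
#' @param intervention_events Alerted events (tibble from
#'   [build_alerts()]/[eligibility_filter()], `alerted` rows).
#' @param control_events Candidate control events (non-alerted pool).
#' @param patients Patients tibble covering both event sets.
#' @param age_tol Maximum absolute age difference in years (default 2).
#' @param period Time-period granularity: `"month"` (default), `"quarter"`,
#'   or `"days"` (then `period_days` bounds the index-date gap).
#' @param period_days Maximum index-date gap in days when
#'   `period = "days"`.
#' @return List with `pairs` (tibble: `pair_id`, `rule_id`, intervention
#'   and control event/patient ids, ages, index dates, `age_gap` = control
#'   minus intervention age) and `unmatched` (intervention events that
#'   found no control).
#' @export
match_cohorts <- function(intervention_events, control_events, patients,
                          age_tol = 2, period = c("month", "quarter", "days"),
                          period_days = 30) {
  period <- match.arg(period)
  if (nrow(control_events) == 0L) {
    warn("empty control pool: no intervention event can be matched")
  }
  annotate <- function(ev) {
    ev %>%
      dplyr::left_join(dplyr::select(patients, "patient_id", "birth_date",
                                     "gender"), by = "patient_id") %>%
      dplyr::mutate(age = age_at(.data$birth_date, .data$index_date),
                    period_key = period_key(.data$index_date, period))
  }
  cases <- annotate(intervention_events)
  ctrls <- annotate(control_events)

  used_ctrl_event <- logical(nrow(ctrls))
  used_ctrl_patient <- character(0)
  rule_order <- cases %>%
    dplyr::count(.data$rule_id, sort = TRUE) %>%
    dplyr::pull(.data$rule_id)
  matches <- vector("list", nrow(cases))
  case_order <- integer(0)

  for (rid in rule_order) {
    case_idx <- which(cases$rule_id == rid)
    case_idx <- case_idx[order(cases$patient_id[case_idx],
                               cases$event_id[case_idx])]
    ctrl_idx_rule <- which(ctrls$rule_id == rid)
    for (i in case_idx) {
      case_order <- c(case_order, i)
      cand <- ctrl_idx_rule[
        !used_ctrl_event[ctrl_idx_rule] &
          !(ctrls$patient_id[ctrl_idx_rule] %in% used_ctrl_patient) &
          ctrls$gender[ctrl_idx_rule] == cases$gender[i] &
          ctrls$lob[ctrl_idx_rule] == cases$lob[i] &
          abs(ctrls$age[ctrl_idx_rule] - cases$age[i]) <= age_tol]
      cand <- if (period == "days") {
        cand[abs(as.integer(ctrls$index_date[cand] - cases$index_date[i])) <= period_days]
      } else {
        cand[ctrls$period_key[cand] == cases$period_key[i]]
      }
      if (length(cand) == 0L) next
      gap <- abs(ctrls$age[cand] - cases$age[i])
      best <- cand[order(gap, ctrls$patient_id[cand], ctrls$event_id[cand])][1L]
      used_ctrl_event[best] <- TRUE
      used_ctrl_patient <- c(used_ctrl_patient, ctrls$patient_id[best])
      matches[[i]] <- best
    }
  }

  matched_case <- which(!vapply(matches, is.null, NA))
  matched_case <- matched_case[order(match(matched_case, case_order))]
  ctrl_rows <- unlist(matches[matched_case])
  pairs <- if (length(matched_case)) {
    tibble::tibble(
      rule_id = cases$rule_id[matched_case],
      intervention_event_id = cases$event_id[matched_case],
      control_event_id = ctrls$event_id[ctrl_rows],
      intervention_patient_id = cases$patient_id[matched_case],
      control_patient_id = ctrls$patient_id[ctrl_rows],
      intervention_index = cases$index_date[matched_case],
      control_index = ctrls$index_date[ctrl_rows],
      intervention_age = cases$age[matched_case],
      control_age = ctrls$age[ctrl_rows],
      age_gap = ctrls$age[ctrl_rows] - cases$age[matched_case],
      gender = cases$gender[matched_case],
      lob = cases$lob[matched_case]
    ) %>%
      dplyr::arrange(.data$rule_id, .data$intervention_event_id) %>%
      dplyr::mutate(pair_id = sprintf("M%05d", dplyr::row_number()), .before = 1L)
  } else {
    empty_pairs()
  }
  unmatched <- cases[setdiff(seq_len(nrow(cases)), matched_case), , drop = FALSE] %>%
    dplyr::select(-"birth_date", -"age", -"period_key", -"gender")
  list(pairs = pairs, unmatched = unmatched)
}

period_key <- function(dates, period) {
  switch(period,
         month = format(dates, "%Y-%m"),
         quarter = paste0(format(dates, "%Y"), "-Q",
                          (as.POSIXlt(dates)$mon %/% 3L) + 1L),
         days = "all")
}

empty_pairs <- function() {
  tibble::tibble(pair_id = character(), rule_id = character(),
                 intervention_event_id = character(), control_event_id = character(),
                 intervention_patient_id = character(), control_patient_id = character(),
                 intervention_index = as.Date(character()),
                 control_index = as.Date(character()),
                 intervention_age = integer(), control_age = integer(),
                 age_gap = integer(), gender = character(), lob = character())
}

#' Per-rule matched-cohort counts
#'
#' @param pairs Pairs tibble from [match_cohorts()].
#' @return Tibble of per-rule pair counts with percentage of total,
#'   descending, plus a `total` row.
#' @export
cohort_summary <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(rule_id = "total", n_pairs = 0L, pct_of_total = NA_real_))
  }
  per_rule <- pairs %>%
    dplyr::count(.data$rule_id, name = "n_pairs", sort = TRUE) %>%
    dplyr::mutate(pct_of_total = 100 * .data$n_pairs / sum(.data$n_pairs))
  dplyr::bind_rows(per_rule,
                   tibble::tibble(rule_id = "total",
                                  n_pairs = sum(per_rule$n_pairs),
                                  pct_of_total = 100))
}
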