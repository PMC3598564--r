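#' Medication-based comorbidity categories
#'
#' The package ships a simplified medication-to-comorbidity lookup in the
#' spirit of claims-based risk stratification models: a dispensing for a
#' drug class listed under a category flags that category as present. It
#' covers the 12 categories used as adjustment covariates in the outcome
#' model (anxiety & tension through irritable bowel syndrome).
#'
#' @param path Optional path to an alternative YAML lookup.
#' @return Tibble: `category`, `display_name`, `class_tags` (list-column).
#' @export
load_rxrisk_map <- function(path = NULL) {
  raw <- yaml::read_yaml(path %||% pddialert_extdata("rxrisk.yaml"))
  tibble::tibble(
    category = vapply(raw$categories, `[[`, "", "category"),
    display_name = vapply(raw$categories, `[[`, "", "display_name"),
    class_tags = lapply(raw$categories, function(x) unlist(x$class_tags))
  )
}

#' Category ids of the built-in comorbidity lookup
#'
#' @return Character vector of category ids.
#' @export
rxrisk_categories <- function() {
  load_rxrisk_map()$category
}

#' Flag comorbidity categories from claims history
#'
#' For each (patient, index date) row, sets a logical flag per category:
#' `TRUE` iff at least one non-reversed claim in the lookback window
#' (default 180 days up to and including the index date) is for a drug
#' whose class tags map to the category. Drugs absent from the dictionary
#' are ignored. Flags are monotone in the claims history: adding claims
#' can only set flags.
#'
#' @param index_tbl Tibble with columns `patient_id` and `index_date`
#'   (other columns pass through).
#' @param claims Claims tibble or `claims_data`.
#' @param bank Rulebank supplying the drug dictionary.
#' @param map Comorbidity lookup ([load_rxrisk_map()] by default).
#' @param lookback Days before the index date to scan (default 180).
#' @return `index_tbl` with one logical column per category appended.
#' @export
assign_rxrisk <- function(index_tbl, claims, bank, map = load_rxrisk_map(),
                          lookback = 180) {
  claims <- if (inherits(claims, "claims_data")) claims$claims else claims
  stopifnot_cols(index_tbl, c("patient_id", "index_date"), "index_tbl")
  live <- dplyr::filter(claims, !.data$reversed)
  # drug -> categories via class tags
  drug_cat <- tidyr::unnest(
    tibble::tibble(drug_id = bank$drugs$drug_id, tag = bank$drugs$class_tags),
    "tag") %>%
    dplyr::inner_join(
      tidyr::unnest(dplyr::select(map, "category", tag = "class_tags"), "tag"),
      by = "tag", relationship = "many-to-many") %>%
    dplyr::distinct(.data$drug_id, .data$category)
  unknown <- setdiff(unique(live$drug_id), bank$drugs$drug_id)
  if (length(unknown)) {
    inform(sprintf("assign_rxrisk: ignoring %d drug id(s) not in dictionary",
                   length(unknown)))
  }
  key_tbl <- dplyr::distinct(index_tbl[, c("patient_id", "index_date")])
  hits <- key_tbl %>%
    dplyr::inner_join(live[, c("patient_id", "drug_id", "fill_date")],
                      by = "patient_id", relationship = "many-to-many") %>%
    dplyr::filter(.data$fill_date >= .data$index_date - lookback,
                  .data$fill_date <= .data$index_date) %>%
    dplyr::inner_join(drug_cat, by = "drug_id", relationship = "many-to-many") %>%
    dplyr::distinct(.data$patient_id, .data$index_date, .data$category) %>%
    dplyr::mutate(flag = TRUE) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "flag",
                       values_fill = FALSE)
  out <- dplyr::left_join(index_tbl, hits, by = c("patient_id", "index_date"))
  for (cat in map$category) {
    if (!cat %in% names(out)) out[[cat]] <- FALSE
    out[[cat]][is.na(out[[cat]])] <- FALSE
  }
  out
}

#' Assemble the regression design frame from pipeline objects
#'
#' Joins outcome records to the covariates of the adjusted logistic model:
#' the alerted (or, for controls, detected) event's prescriber type and
#' specialist flag, whether the second interacting drug is an acute (non
#' maintenance) medication, the rule's severity level, patient gender and
#' age group at index, and the comorbidity category flags from the 180-day
#' claims lookback. One row per matched event.
#'
#' @param records Outcome records from [ascertain_changes()].
#' @param events Event table the records reference.
#' @param data `claims_data` with patients and prescribers.
#' @param bank Rulebank.
#' @return Tibble ready for [fit_outcome_model()].
#' @export
prepare_regression_data <- function(records, events, data, bank) {
  maintenance <- setNames(bank$drugs$maintenance, bank$drugs$drug_id)
  severity <- setNames(vapply(bank$rules, `[[`, "", "severity"),
                       names(bank$rules))
  df <- records %>%
    dplyr::left_join(dplyr::select(events, "event_id", "second_drug_id",
                                   "alert_prescriber"), by = "event_id") %>%
    dplyr::left_join(dplyr::select(data$patients, "patient_id", "birth_date",
                                   "gender"), by = "patient_id") %>%
    dplyr::left_join(dplyr::select(data$prescribers, "prescriber_id",
                                   "practitioner_type", "primary_care"),
                     by = c(alert_prescriber = "prescriber_id")) %>%
    dplyr::mutate(
      intervention = as.integer(.data$arm == "intervention"),
      male = .data$gender == "M",
      age = age_at(.data$birth_date, .data$index_date),
      age_group = cut(.data$age, breaks = c(-1, 49, 64, 79, Inf),
                      labels = c("0-49", "50-64", "65-79", "80+")),
      age_group = as.character(.data$age_group),
      specialist = !.data$primary_care,
      acute_medication = !maintenance[.data$second_drug_id],
      severity = severity[.data$rule_id]
    ) %>%
    dplyr::select(-"birth_date", -"gender", -"age")
  assign_rxrisk(df, data$claims, bank)
}
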