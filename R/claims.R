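#' Read a pharmacy claims dataset
#'
#' Loads the three study tables from CSV — patients, prescribers, and
#' dispensing claims — types them, and enforces referential integrity.
#' Reversed (voided) claims are retained in memory but flagged; every
#' downstream stage excludes them.
#'
#' Expected headers (extra columns are preserved):
#' \describe{
#'   \item{patients.csv}{`patient_id,birth_date,gender,lob,eligibility_start,eligibility_end`
#'     and optionally `plan` (alert-enabled plan code; defaults to `"A"`).}
#'   \item{prescribers.csv}{`prescriber_id,practitioner_type,primary_specialty`.}
#'   \item{claims.csv}{`claim_id,patient_id,drug_id,fill_date,days_supply,prescriber_id,lob,reversed`.}
#' }
#' Dates are ISO-8601. `gender` is `F`/`M`; `lob` is
#' `commercial`/`medicaid`; `practitioner_type` is one of `physician`,
#' `nurse_practitioner`, `physician_assistant`, `other`. A prescriber is a
#' primary-care practitioner iff the primary specialty is internal
#' medicine, general practice, or family practice (derived column
#' `primary_care`).
#'
#' @param dir Directory containing `patients.csv`, `prescribers.csv`,
#'   `claims.csv`; or a named list/vector with elements `patients`,
#'   `prescribers`, `claims` giving explicit paths.
#' @return A `claims_data` object: list of tibbles `patients`,
#'   `prescribers`, `claims`.
#' @export
read_claims <- function(dir) {
  paths <- if (is.character(dir) && length(dir) == 1L && dir.exists(dir)) {
    list(patients = file.path(dir, "patients.csv"),
         prescribers = file.path(dir, "prescribers.csv"),
         claims = file.path(dir, "claims.csv"))
  } else {
    as.list(dir)
  }
  stopifnot(all(c("patients", "prescribers", "claims") %in% names(paths)))
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  claims_data(patients = rd(paths$patients),
              prescribers = rd(paths$prescribers),
              claims = rd(paths$claims))
}

#' Assemble and validate a claims dataset from in-memory tables
#'
#' @param patients,prescribers,claims Data frames with the schemas
#'   documented in [read_claims()].
#' @return A validated `claims_data` object.
#' @export
claims_data <- function(patients, prescribers, claims) {
  stopifnot_cols(patients, c("patient_id", "birth_date", "gender", "lob",
                             "eligibility_start", "eligibility_end"), "patients")
  stopifnot_cols(prescribers, c("prescriber_id", "practitioner_type",
                                "primary_specialty"), "prescribers")
  stopifnot_cols(claims, c("claim_id", "patient_id", "drug_id", "fill_date",
                           "days_supply", "prescriber_id", "lob", "reversed"),
                 "claims")
  patients <- tibble::as_tibble(patients) %>%
    dplyr::mutate(
      patient_id = as.character(.data$patient_id),
      birth_date = as_date_strict(.data$birth_date, "birth_date"),
      gender = check_enum(.data$gender, c("F", "M"), "gender"),
      lob = check_enum(.data$lob, c("commercial", "medicaid"), "lob"),
      eligibility_start = as_date_strict(.data$eligibility_start, "eligibility_start"),
      eligibility_end = as_date_strict(.data$eligibility_end, "eligibility_end")
    )
  if (!"plan" %in% names(patients)) patients$plan <- "A"
  if (any(patients$eligibility_end < patients$eligibility_start)) {
    abort("patient eligibility_end precedes eligibility_start",
          class = "pddialert_schema_error")
  }
  if (anyDuplicated(patients$patient_id)) {
    abort("duplicate patient_id", class = "pddialert_integrity_error")
  }
  prescribers <- tibble::as_tibble(prescribers) %>%
    dplyr::mutate(
      prescriber_id = as.character(.data$prescriber_id),
      practitioner_type = check_enum(.data$practitioner_type,
                                     c("physician", "nurse_practitioner",
                                       "physician_assistant", "other"),
                                     "practitioner_type"),
      primary_specialty = as.character(.data$primary_specialty),
      primary_care = tolower(.data$primary_specialty) %in%
        c("internal medicine", "general practice", "family practice")
    )
  if (anyDuplicated(prescribers$prescriber_id)) {
    abort("duplicate prescriber_id", class = "pddialert_integrity_error")
  }
  claims <- tibble::as_tibble(claims) %>%
    dplyr::mutate(
      claim_id = as.character(.data$claim_id),
      patient_id = as.character(.data$patient_id),
      drug_id = as.character(.data$drug_id),
      fill_date = as_date_strict(.data$fill_date, "fill_date"),
      days_supply = as.integer(.data$days_supply),
      prescriber_id = as.character(.data$prescriber_id),
      lob = check_enum(.data$lob, c("commercial", "medicaid"), "lob"),
      reversed = as.logical(.data$reversed)
    )
  if (any(claims$days_supply < 1L, na.rm = TRUE) || anyNA(claims$days_supply)) {
    abort("claims: days_supply must be a positive integer",
          class = "pddialert_schema_error")
  }
  dangling_p <- setdiff(claims$patient_id, patients$patient_id)
  if (length(dangling_p)) {
    abort(sprintf("claims reference unknown patient_id(s): %s",
                  paste(head(dangling_p, 5L), collapse = ", ")),
          class = "pddialert_integrity_error")
  }
  dangling_rx <- setdiff(claims$prescriber_id, prescribers$prescriber_id)
  if (length(dangling_rx)) {
    abort(sprintf("claims reference unknown prescriber_id(s): %s",
                  paste(head(dangling_rx, 5L), collapse = ", ")),
          class = "pddialert_integrity_error")
  }
  structure(list(patients = patients, prescribers = prescribers, claims = claims),
            class = "claims_data")
}

check_enum <- function(x, levels, field) {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% levels
  if (any(bad)) {
    abort(sprintf("field '%s': invalid value '%s' (allowed: %s)",
                  field, x[which(bad)[1]], paste(levels, collapse = ", ")),
          class = "pddialert_schema_error")
  }
  x
}

#' Write a claims dataset to CSV
#'
#' Inverse of [read_claims()]; `read_claims(write_claims(x, d))` round-trips
#' losslessly.
#'
#' @param x A `claims_data` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_claims <- function(x, dir) {
  stopifnot(inherits(x, "claims_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$patients, file.path(dir, "patients.csv"), progress = FALSE)
  readr::write_csv(dplyr::select(x$prescribers, -dplyr::any_of("primary_care")),
                   file.path(dir, "prescribers.csv"), progress = FALSE)
  readr::write_csv(x$claims, file.path(dir, "claims.csv"), progress = FALSE)
  invisible(dir)
}

#' @export
print.claims_data <- function(x, ...) {
  cat(sprintf("<claims_data> %d patients, %d prescribers, %d claims (%d reversed)\n",
              nrow(x$patients), nrow(x$prescribers), nrow(x$claims),
              sum(x$claims$reversed)))
  invisible(x)
}

#' Active supply window of claims
#'
#' Concurrent exposure is operationalized as overlap of active-supply
#' windows: a fill covers the half-open interval
#' `[fill_date, fill_date + days_supply)`, day resolution.
#'
#' @param claims Claims tibble (non-reversed rows are the meaningful input).
#' @return The claims with `window_start` and `window_end` columns appended
#'   (`window_end` exclusive).
#' @export
active_supply_window <- function(claims) {
  dplyr::mutate(claims,
                window_start = .data$fill_date,
                window_end = .data$fill_date + .data$days_supply)
}

#' Completed age in years at an index date
#'
#' @param birth_date,index Date vectors (recycled).
#' @return Integer vector of completed years.
#' @examples
#' age_at(as.Date("1945-06-01"), as.Date("2010-05-31")) # 64
#' age_at(as.Date("1945-06-01"), as.Date("2010-06-01")) # 65
#' @export
age_at <- function(birth_date, index) {
  birth_date <- as_date_strict(birth_date, "birth_date")
  index <- as_date_strict(index, "index")
  if (any(index < birth_date, na.rm = TRUE)) {
    abort("index date precedes birth date", class = "pddialert_data_error")
  }
  by <- as.POSIXlt(birth_date)
  ix <- as.POSIXlt(index)
  age <- ix$year - by$year
  before_birthday <- ix$mon < by$mon | (ix$mon == by$mon & ix$mday < by$mday)
  as.integer(age - before_birthday)
}
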