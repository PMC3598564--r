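#' Run the full fax-alert evaluation pipeline
#'
#' Orchestrates simulate -> detect -> alert -> eligibility -> match ->
#' ascertain -> analyse on synthetic data, writing every intermediate and
#' final artifact plus a manifest to `out_dir`. Stage-level counts (claims
#' read, events detected, alerts sent, 90-day-eligible, matched pairs,
#' successes) are logged so every run has the programme's attrition chain
#' as a synthetic analogue. Re-running with the same configuration and
#' seed reproduces every results file identically.
#'
#' @param sim A [sim_config()]; its seed drives all randomness.
#' @param out_dir Output directory (created if needed).
#' @param bank Rulebank (default built-in).
#' @param seed Optional integer overriding `sim$seed`.
#' @param period Matching time-period granularity (`"month"`, `"quarter"`,
#'   `"days"`).
#' @param outcome_window Days of the change-ascertainment window (90).
#' @param eligibility_horizon Days of required post-index eligibility (90).
#' @param incident_only Restrict detection to incident second fills.
#' @param strict_switch,incident_alternative Outcome flags, see
#'   [ascertain_changes()].
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with every stage's objects: `sim`, `events`,
#'   `alerts`, `eligible`, `match` (pairs + unmatched), `records`,
#'   `results`, `demographics`, `model`, `manifest`.
#' @export
run_pipeline <- function(sim = sim_config(), out_dir, bank = load_rulebank(),
                         seed = NULL, period = "month", outcome_window = 90,
                         eligibility_horizon = 90, incident_only = FALSE,
                         strict_switch = FALSE, incident_alternative = FALSE,
                         quiet = FALSE) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "pddialert_stage_error", parent = e)
    })
  }

  simres <- stage("simulate", {
    s <- simulate_population(sim, bank)
    write_simulation(s, file.path(out_dir, "input"))
    s
  })
  data <- simres$data
  say("simulate: %d patients, %d claims (%d reversed)",
      nrow(data$patients), nrow(data$claims), sum(data$claims$reversed))

  events <- stage("detect", {
    detect_events(data, bank, scan_window = c(sim$study_start, sim$study_end),
                  incident_only = incident_only)
  })
  say("detect: %d co-exposure events", nrow(events))

  alerts <- stage("alerts", build_alerts(events, bank, alert_plans = "A"))
  n_alerts <- sum(alerts$alerted)
  say("alerts: %d fax alerts sent (of %d events)", n_alerts, nrow(alerts))

  eligible <- stage("eligibility", {
    eligibility_filter(alerts, data$patients, horizon = eligibility_horizon)
  })
  n_elig <- sum(eligible$alerted)
  say("eligibility: %d alerts with >= %d days of eligibility", n_elig,
      eligibility_horizon)

  intervention <- dplyr::filter(eligible, .data$alerted, .data$evaluable)
  control_pool <- dplyr::filter(eligible, .data$plan != "A", .data$evaluable)
  say("cohorts: %d evaluable intervention events, %d control-pool events",
      nrow(intervention), nrow(control_pool))

  matched <- stage("match", {
    match_cohorts(intervention, control_pool, data$patients, period = period)
  })
  say("match: %d pairs (%d intervention events unmatched)",
      nrow(matched$pairs), nrow(matched$unmatched))

  records <- stage("ascertain", {
    ascertain_changes(matched$pairs, events, data, bank,
                      window = outcome_window, strict_switch = strict_switch,
                      incident_alternative = incident_alternative)
  })
  results <- stage("analyze", pair_results(records))
  say("analyze: %d intervention and %d control successes",
      results$changes_intervention[results$rule_id == "total"],
      results$changes_control[results$rule_id == "total"])

  demographics <- stage("demographics", {
    demographics_table(dplyr::filter(eligible, .data$alerted), data$patients)
  })
  model <- stage("regression", {
    tryCatch(
      fit_outcome_model(prepare_regression_data(records, events, data, bank)),
      pddialert_model_error = function(e) {
        warn(sprintf("regression skipped: %s", conditionMessage(e)))
        NULL
      })
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("pddialert")),
    seed = sim$seed,
    config = serialize_config(sim),
    flags = list(period = period, outcome_window = outcome_window,
                 eligibility_horizon = eligibility_horizon,
                 incident_only = incident_only, strict_switch = strict_switch,
                 incident_alternative = incident_alternative),
    attrition = list(
      claims = nrow(data$claims),
      events_detected = nrow(events),
      alerts_sent = n_alerts,
      alerts_eligible_90d = n_elig,
      evaluable_intervention_events = nrow(intervention),
      matched_pairs = nrow(matched$pairs),
      successes_intervention =
        results$changes_intervention[results$rule_id == "total"],
      successes_control = results$changes_control[results$rule_id == "total"])
  )

  readr::write_csv(events, file.path(out_dir, "events.csv"), progress = FALSE)
  readr::write_csv(matched$pairs, file.path(out_dir, "pairs.csv"), progress = FALSE)
  readr::write_csv(records, file.path(out_dir, "outcomes.csv"), progress = FALSE)
  readr::write_csv(results, file.path(out_dir, "pair_results.csv"), progress = FALSE)
  readr::write_csv(demographics, file.path(out_dir, "demographics.csv"),
                   progress = FALSE)
  readr::write_csv(cohort_summary(matched$pairs),
                   file.path(out_dir, "cohort_summary.csv"), progress = FALSE)
  if (!is.null(model)) {
    readr::write_csv(model$tidy, file.path(out_dir, "regression.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sim = simres, events = events, alerts = alerts,
                 eligible = eligible, match = matched, records = records,
                 results = results, demographics = demographics, model = model,
                 manifest = manifest))
}

serialize_config <- function(sim) {
  out <- unclass(sim)
  out$study_start <- as.character(out$study_start)
  out$study_end <- as.character(out$study_end)
  out$co_rx_rate <- as.list(out$co_rx_rate)
  out$baseline_change_prob <- as.list(out$baseline_change_prob)
  out$age_mix <- as.list(out$age_mix)
  out$prescriber_mix <- as.list(out$prescriber_mix)
  out
}

#' Demographic summary of alerted events
#'
#' Age-stratum, gender, and line-of-business composition of the alerted
#' events (one row per alert, as programmes report it), aggregated and per
#' line of business.
#'
#' @param events Alerted events.
#' @param patients Patients tibble.
#' @return Tibble: `section`, `level`, `n`, `pct`, `n_commercial`,
#'   `n_medicaid`.
#' @export
demographics_table <- function(events, patients) {
  if (nrow(events) == 0L) {
    return(tibble::tibble(section = character(), level = character(),
                          n = integer(), pct = double(),
                          n_commercial = integer(), n_medicaid = integer()))
  }
  df <- events %>%
    dplyr::left_join(dplyr::select(patients, "patient_id", "birth_date",
                                   "gender"), by = "patient_id") %>%
    dplyr::mutate(
      age = age_at(.data$birth_date, .data$index_date),
      age_stratum = cut(.data$age, breaks = c(-1, 17, 39, 64, Inf),
                        labels = c("<18", "18-39", "40-64", ">=65")),
      age_stratum = as.character(.data$age_stratum),
      gender_label = dplyr::if_else(.data$gender == "F", "Female", "Male"))
  one_section <- function(var, section) {
    df %>%
      dplyr::count(level = .data[[var]], .data$lob) %>%
      tidyr::pivot_wider(names_from = "lob", values_from = "n",
                         values_fill = 0L, names_prefix = "n_") %>%
      dplyr::mutate(section = section)
  }
  out <- dplyr::bind_rows(one_section("age_stratum", "age"),
                          one_section("gender_label", "gender"),
                          one_section("lob", "lob"))
  for (col in c("n_commercial", "n_medicaid")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out %>%
    dplyr::mutate(n = .data$n_commercial + .data$n_medicaid,
                  pct = 100 * .data$n / nrow(df)) %>%
    dplyr::select("section", "level", "n", "pct", "n_commercial", "n_medicaid")
}

#' Render a human-readable run report
#'
#' Formats the demographics, per-pair comparison, cohort summary, and
#' regression tables of a completed run directory as markdown. Every
#' number is read from the results CSVs; nothing is recomputed.
#'
#' @param results_dir Directory written by [run_pipeline()].
#' @param file Optional path to also write the report to.
#' @return Character vector of report lines, invisibly.
#' @export
render_report <- function(results_dir, file = NULL) {
  need <- file.path(results_dir, c("pair_results.csv", "demographics.csv",
                                   "manifest.json"))
  if (!all(file.exists(need))) {
    abort(sprintf("results directory '%s' is missing: %s", results_dir,
                  paste(basename(need[!file.exists(need)]), collapse = ", ")),
          class = "pddialert_data_error")
  }
  rd <- function(f) readr::read_csv(file.path(results_dir, f),
                                    show_col_types = FALSE, progress = FALSE)
  results <- rd("pair_results.csv")
  demographics <- rd("demographics.csv")
  manifest <- jsonlite::read_json(file.path(results_dir, "manifest.json"))
  lines <- c("# Fax-alert PDDI intervention: run report", "")
  at <- manifest$attrition
  lines <- c(lines, "## Attrition", "",
             sprintf("- claims scanned: %s", at$claims),
             sprintf("- co-exposure events detected: %s", at$events_detected),
             sprintf("- fax alerts sent: %s", at$alerts_sent),
             sprintf("- alerts with 90-day eligibility: %s", at$alerts_eligible_90d),
             sprintf("- evaluable intervention events: %s",
                     at$evaluable_intervention_events),
             sprintf("- matched pairs: %s", at$matched_pairs), "")
  if (nrow(results) == 0L) {
    return(invisible(c(lines, "No events: nothing to report.")))
  }
  lines <- c(lines, "## Patient demographics (alerted events)", "",
             "| Section | Level | N | % |", "|---|---|---:|---:|",
             sprintf("| %s | %s | %d | %.1f |", demographics$section,
                     demographics$level, demographics$n, demographics$pct), "")
  fmt_p <- function(p) ifelse(p >= 0.995, "1.0", sprintf("%.2f", p))
  lines <- c(lines, "## Successful 90-day therapy changes by PDDI", "",
             "| PDDI | N/arm | Intervention changes (%) | Control changes (%) | Test | p |",
             "|---|---:|---:|---:|---|---:|",
             sprintf("| %s | %d | %d (%.1f%%) | %d (%.1f%%) | %s | %s |",
                     results$rule_id, results$n_per_arm,
                     results$changes_intervention, 100 * results$rate_intervention,
                     results$changes_control, 100 * results$rate_control,
                     results$test_used, fmt_p(results$p_value)), "",
             "Test choice: Fisher exact when the minimum expected cell count is <= 5, otherwise uncorrected Pearson chi-square.", "")
  reg_path <- file.path(results_dir, "regression.csv")
  if (file.exists(reg_path)) {
    reg <- rd("regression.csv")
    lines <- c(lines, "## Adjusted logistic model of successful change", "",
               "| Term | Coef | p | OR | 95% CI |", "|---|---:|---:|---:|---|",
               sprintf("| %s | %.4f | %.4f | %.3f | %.3f-%.3f |", reg$term,
                       reg$estimate, reg$p_value, reg$odds_ratio, reg$or_lower,
                       reg$or_upper), "")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
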