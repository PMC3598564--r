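#' Choose between chi-square and Fisher's exact test for a 2x2 table
#'
#' The small-sample rule is driven by expected cell counts: Fisher's exact
#' test when the minimum expected count (row total x column total / N) is
#' at most 5, otherwise the uncorrected Pearson chi-square. A zero margin
#' forces Fisher (the chi-square statistic is undefined there).
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (rows = arms, columns = changed / not changed).
#' @return `"chi_square"` or `"fisher_exact"`.
#' @examples
#' choose_test(matrix(c(8, 4, 2, 10), 2, byrow = TRUE))   # fisher_exact
#' choose_test(matrix(c(8, 161, 3, 166), 2, byrow = TRUE)) # chi_square
#' @export
choose_test <- function(table) {
  check_2x2(table)
  n <- sum(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return("fisher_exact")
  }
  expected <- outer(rowSums(table), colSums(table)) / n
  if (min(expected) <= 5) "fisher_exact" else "chi_square"
}

check_2x2 <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L)) {
    abort("expected a 2x2 matrix of counts", class = "pddialert_data_error")
  }
  if (any(table < 0) || any(table != round(table))) {
    abort("table counts must be non-negative integers",
          class = "pddialert_data_error")
  }
  if (sum(table) == 0) {
    abort("all-zero 2x2 table: comparison undefined",
          class = "pddialert_data_error")
  }
  invisible(table)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conventional two-sided definition: the sum of probabilities of all
#' tables with the observed margins whose hypergeometric point probability
#' does not exceed that of the observed table (within a relative tolerance
#' of 1e-7 to absorb floating-point ties).
#'
#' @param table 2x2 count matrix.
#' @return p-value in \[0, 1\].
#' @export
fisher_exact_p <- function(table) {
  check_2x2(table)
  a <- table[1, 1]
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1]); n <- sum(table)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  d <- dhyper(support, c1, n - c1, r1)
  obs <- dhyper(a, c1, n - c1, r1)
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Compare change rates between two arms
#'
#' Applies [choose_test()] and computes the p-value: uncorrected Pearson
#' chi-square (df = 1, upper tail) or the two-sided Fisher exact test.
#'
#' @param table 2x2 count matrix (rows = arms, columns = changed / not).
#' @return List with `test_used` and `p_value`.
#' @examples
#' compare_arms(matrix(c(154, 1865, 132, 1887), 2, byrow = TRUE))$p_value # 0.177
#' @export
compare_arms <- function(table) {
  test <- choose_test(table)
  p <- if (test == "fisher_exact") {
    fisher_exact_p(table)
  } else {
    suppressWarnings(chisq.test(table, correct = FALSE)$p.value)
  }
  list(test_used = test, p_value = as.numeric(p))
}

#' Per-rule and pooled comparison table
#'
#' Builds the per-PDDI comparison of 90-day change rates between the
#' intervention and control arms, plus a pooled `total` row (a single 2x2
#' over all matched events, unstratified). Matched-pair dependence is
#' ignored (unconditional tests), matching standard retrospective-DUR
#' reporting; set `mcnemar = TRUE` for a conditional McNemar analysis as
#' an extension.
#'
#' @param records Outcome records from [ascertain_changes()].
#' @param mcnemar Use McNemar's test on discordant pairs instead of the
#'   unconditional tests (default `FALSE`).
#' @return Tibble: `rule_id`, `n_per_arm`, `changes_intervention`,
#'   `changes_control`, `rate_intervention`, `rate_control`, `test_used`,
#'   `p_value`; one row per rule, descending `n_per_arm`, plus `total`.
#' @export
pair_results <- function(records, mcnemar = FALSE) {
  counts <- records %>%
    dplyr::group_by(.data$rule_id) %>%
    dplyr::summarise(
      n_per_arm = sum(.data$arm == "intervention"),
      changes_intervention = sum(.data$success & .data$arm == "intervention"),
      changes_control = sum(.data$success & .data$arm == "control"),
      .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$n_per_arm), .data$rule_id)
  counts <- dplyr::bind_rows(
    counts,
    dplyr::summarise(counts, rule_id = "total",
                     n_per_arm = sum(.data$n_per_arm),
                     changes_intervention = sum(.data$changes_intervention),
                     changes_control = sum(.data$changes_control)))
  if (!mcnemar) {
    return(pair_results_from_counts(counts))
  }
  wide <- records %>%
    dplyr::select("pair_id", "rule_id", "arm", "success") %>%
    tidyr::pivot_wider(names_from = "arm", values_from = "success")
  mc_p <- function(w) {
    b <- sum(w$intervention & !w$control)
    c <- sum(!w$intervention & w$control)
    if (b + c == 0) return(1)
    stats::binom.test(b, b + c, 0.5)$p.value
  }
  per_rule <- wide %>%
    dplyr::group_by(.data$rule_id) %>%
    dplyr::group_modify(~ tibble::tibble(p_value = mc_p(.x))) %>%
    dplyr::ungroup()
  counts %>%
    dplyr::mutate(rate_intervention = .data$changes_intervention / .data$n_per_arm,
                  rate_control = .data$changes_control / .data$n_per_arm,
                  test_used = "mcnemar_exact") %>%
    dplyr::left_join(dplyr::bind_rows(per_rule,
                                      tibble::tibble(rule_id = "total",
                                                     p_value = mc_p(wide))),
                     by = "rule_id")
}

#' Comparison table from bare per-rule counts
#'
#' Same inference as [pair_results()] but starting from a counts table
#' (e.g. a published comparison table re-analysed, or counts assembled
#' elsewhere).
#'
#' @param counts Tibble with columns `rule_id`, `n_per_arm`,
#'   `changes_intervention`, `changes_control`.
#' @return The counts with `rate_intervention`, `rate_control`,
#'   `test_used`, `p_value` appended.
#' @export
pair_results_from_counts <- function(counts) {
  stopifnot_cols(counts, c("rule_id", "n_per_arm", "changes_intervention",
                           "changes_control"), "counts")
  res <- purrr::pmap(
    dplyr::select(counts, "n_per_arm", "changes_intervention", "changes_control"),
    function(n_per_arm, changes_intervention, changes_control) {
      tab <- matrix(c(changes_intervention, n_per_arm - changes_intervention,
                      changes_control, n_per_arm - changes_control),
                    nrow = 2, byrow = TRUE)
      cmp <- compare_arms(tab)
      tibble::tibble(test_used = cmp$test_used, p_value = cmp$p_value)
    }) %>% dplyr::bind_rows()
  counts %>%
    dplyr::mutate(rate_intervention = .data$changes_intervention / .data$n_per_arm,
                  rate_control = .data$changes_control / .data$n_per_arm) %>%
    dplyr::bind_cols(res)
}

#' Benchmark per-rule change counts from a published fax-alert programme
#'
#' Matched-cohort counts (events per arm, 90-day changes per arm) and the
#' p-values printed in the source programme's comparison table, shipped as
#' a reference input for re-analysis and regression testing of the
#' inference stage.
#'
#' @return Tibble: `rule_id`, `n_per_arm`, `changes_intervention`,
#'   `changes_control`, `published_p`; 13 rules plus `total`.
#' @export
published_change_counts <- function() {
  readr::read_csv(pddialert_extdata("published_change_counts.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Covariate-adjusted logistic model of successful change
#'
#' Fits, by maximum likelihood, a logistic regression of the binary
#' successful-change outcome on the intervention indicator and the
#' adjustment covariates: specialist prescriber, practitioner type
#' (reference: physician), acute medication, interaction severity level
#' (reference: moderate), male gender, patient age group (reference:
#' 65-79), and the medication-based comorbidity category indicators.
#' Covariates absent from `records` are silently dropped from the model,
#' so the same function serves both the fully adjusted and the
#' intervention-only analysis.
#'
#' @param records Data frame with logical/0-1 column `success`, column
#'   `intervention` (0/1) or `arm`, and any of: `specialist`,
#'   `practitioner_type`, `acute_medication`, `severity`, `male`,
#'   `age_group`, plus comorbidity flag columns named by category.
#' @return Object of class `ddi_outcome_model`: list with `fit` (the glm)
#'   and `tidy`, a tibble of `term`, `estimate`, `std_error`, `p_value`,
#'   `odds_ratio`, `or_lower`, `or_upper` (Wald 95% CI).
#' @export
fit_outcome_model <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"intervention" %in% names(records)) {
    if (!"arm" %in% names(records)) {
      abort("records need an 'intervention' (0/1) or 'arm' column",
            class = "pddialert_data_error")
    }
    records$intervention <- as.integer(records$arm == "intervention")
  }
  if (!"success" %in% names(records)) {
    abort("records need a 'success' column", class = "pddialert_data_error")
  }
  records$success <- as.logical(records$success)
  if (all(!records$success) || all(records$success)) {
    abort("degenerate outcome: all records share one outcome value",
          class = "pddialert_model_error")
  }
  if ("practitioner_type" %in% names(records)) {
    records$practitioner_type <- stats::relevel(
      factor(records$practitioner_type), ref = "physician")
  }
  if ("severity" %in% names(records)) {
    lev <- intersect(c("moderate", "major", "minor"),
                     unique(records$severity))
    records$severity <- factor(records$severity, levels = lev)
  }
  if ("age_group" %in% names(records)) {
    records$age_group <- stats::relevel(factor(records$age_group), ref = "65-79")
  }
  fixed <- c("specialist", "practitioner_type", "acute_medication",
             "severity", "male", "age_group")
  covs <- c(intersect(fixed, names(records)),
            intersect(rxrisk_categories(), names(records)))
  # drop constant covariates (inestimable)
  keep <- vapply(covs, function(v) length(unique(records[[v]])) > 1L, NA)
  rhs <- c("intervention", covs[keep])
  form <- stats::as.formula(paste("success ~", paste(rhs, collapse = " + ")))
  fit <- glm(form, family = binomial(), data = records)
  if (!fit$converged) {
    abort("logistic model did not converge", class = "pddialert_model_error")
  }
  cf <- summary(fit)$coefficients
  if (any(abs(cf[, "Estimate"]) > 15) || any(cf[, "Std. Error"] > 100)) {
    warn("possible separation: extreme coefficient or standard error in logistic fit")
  }
  z <- qnorm(0.975)
  tidy <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    p_value = cf[, "Pr(>|z|)"],
    odds_ratio = exp(cf[, "Estimate"]),
    or_lower = exp(cf[, "Estimate"] - z * cf[, "Std. Error"]),
    or_upper = exp(cf[, "Estimate"] + z * cf[, "Std. Error"])
  )
  structure(list(fit = fit, tidy = tidy), class = "ddi_outcome_model")
}

#' @export
print.ddi_outcome_model <- function(x, ...) {
  cat("<ddi_outcome_model> logistic model of successful change\n")
  print(x$tidy, n = nrow(x$tidy))
  invisible(x)
}
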