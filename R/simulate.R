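#' Simulation configuration
#'
#' Bundles every knob of the synthetic claims generator. The defaults are
#' the study conditions of the fax-alert programme the package models: a
#' large commercial plan and a small managed Medicaid plan (89.7% / 10.3%
#' of alerts), an elderly-skewed age mix (69.7% aged 65+), 53.7% female,
#' per-rule co-prescription rates proportional to the programme's matched
#' alert mix, per-rule baseline 90-day change probabilities equal to the
#' programme's control-arm change rates, and an intervention effect on the
#' odds scale defaulting to the pooled crude odds ratio observed in the
#' programme (~1.18).
#'
#' @param seed Integer RNG seed; the generator is fully deterministic given
#'   the seed.
#' @param n_patients_commercial,n_patients_medicaid Patients in the
#'   alert-enabled plan ("A"), by line of business.
#' @param control_pool_multiplier Size of the control-pool plan ("B")
#'   relative to plan A, per line of business. The default (3) reflects
#'   that controls are drawn from several other health plans managed by
#'   the same claims processor, a pool larger than the alerted plan;
#'   it is the smallest integer multiple at which every evaluable cohort
#'   — including the rarest, with only a handful of alerts — finds
#'   matches, as every cohort did in the programme.
#' @param study_start,study_end Six-month detection window (dates).
#' @param co_rx_rate Named per-rule probability that a plan member is
#'   co-prescribed that rule's drug pair during the window. `NULL` uses the
#'   default mix (see [default_co_rx_rates()]).
#' @param baseline_change_prob Named per-evaluable-rule probability of
#'   initiating a recommended alternative within 90 days absent
#'   intervention. `NULL` uses the control-arm change rates of the
#'   programme's published comparison table.
#' @param intervention_odds_ratio Multiplicative effect on the change odds
#'   for alerted events.
#' @param eligible_90d_frac Fraction of event patients whose plan
#'   eligibility extends at least 90 days past the index fill (programme:
#'   7101/8075 = 0.879).
#' @param age_mix Stratum weights for ages <18, 18-39, 40-64, >=65 (sum 1).
#' @param female_frac Probability a patient is female.
#' @param prescriber_mix Weights over practitioner types
#'   (physician, nurse_practitioner, physician_assistant, other).
#' @param primary_care_frac Probability a prescriber's primary specialty is
#'   internal medicine, general practice, or family practice.
#' @param n_prescribers Prescriber pool size.
#' @param noise_rate Background (non-rule) dispensings per patient-year.
#' @param noise_reversal_rate Fraction of background claims reversed
#'   (voided); reversals are confined to background claims so the recorded
#'   ground truth stays exact.
#' @param suppress_medicaid_benzo_azole If `TRUE` (default) no
#'   benzodiazepine-azole co-prescriptions are generated in the Medicaid
#'   stream, mirroring that plan's alert exclusion.
#' @param education_co_rx_rate Co-prescription rate for each of the five
#'   education-only rules (no published per-rule counts exist; this keeps
#'   total alerts > evaluable alerts as in the programme).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 20100501L,
                       n_patients_commercial = 4485L,
                       n_patients_medicaid = 515L,
                       control_pool_multiplier = 3,
                       study_start = as.Date("2010-05-01"),
                       study_end = as.Date("2010-10-31"),
                       co_rx_rate = NULL,
                       baseline_change_prob = NULL,
                       intervention_odds_ratio = 1.18,
                       eligible_90d_frac = 0.879,
                       age_mix = c(under_18 = 0.002, age_18_39 = 0.019,
                                   age_40_64 = 0.282, age_65_plus = 0.697),
                       female_frac = 0.537,
                       prescriber_mix = c(physician = 0.872,
                                          nurse_practitioner = 0.064,
                                          physician_assistant = 0.044,
                                          other = 0.020),
                       primary_care_frac = 0.466,
                       n_prescribers = 600L,
                       noise_rate = 5,
                       noise_reversal_rate = 0.02,
                       suppress_medicaid_benzo_azole = TRUE,
                       education_co_rx_rate = 0.04) {
  co_rx_rate <- co_rx_rate %||% default_co_rx_rates(education_co_rx_rate)
  baseline_change_prob <- baseline_change_prob %||% default_baseline_change_probs()
  cfg <- list(seed = as.integer(seed),
              n_patients_commercial = as.integer(n_patients_commercial),
              n_patients_medicaid = as.integer(n_patients_medicaid),
              control_pool_multiplier = control_pool_multiplier,
              study_start = as.Date(study_start), study_end = as.Date(study_end),
              co_rx_rate = co_rx_rate,
              baseline_change_prob = baseline_change_prob,
              intervention_odds_ratio = intervention_odds_ratio,
              eligible_90d_frac = eligible_90d_frac,
              age_mix = age_mix, female_frac = female_frac,
              prescriber_mix = prescriber_mix,
              primary_care_frac = primary_care_frac,
              n_prescribers = as.integer(n_prescribers),
              noise_rate = noise_rate,
              noise_reversal_rate = noise_reversal_rate,
              suppress_medicaid_benzo_azole = suppress_medicaid_benzo_azole,
              education_co_rx_rate = education_co_rx_rate)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$co_rx_rate, cfg$baseline_change_prob, cfg$eligible_90d_frac,
             cfg$female_frac, cfg$primary_care_frac, cfg$noise_reversal_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("sim_config: probabilities must lie in [0, 1]", class = "pddialert_config_error")
  }
  if (cfg$intervention_odds_ratio <= 0) {
    abort("sim_config: intervention_odds_ratio must be positive",
          class = "pddialert_config_error")
  }
  if (abs(sum(cfg$age_mix) - 1) > 1e-6) {
    abort("sim_config: age_mix weights must sum to 1", class = "pddialert_config_error")
  }
  if (cfg$study_end <= cfg$study_start) {
    abort("sim_config: study_end must follow study_start", class = "pddialert_config_error")
  }
  n_total <- cfg$n_patients_commercial + cfg$n_patients_medicaid
  if (n_total == 0L && any(cfg$co_rx_rate > 0)) {
    abort("sim_config: positive co-prescription rates but zero patients",
          class = "pddialert_config_error")
  }
  invisible(cfg)
}

#' Default per-rule co-prescription rates
#'
#' Rates for the 13 evaluable rules are proportional to the programme's
#' matched alert mix (e.g. warfarin + statins was 46.5% of matched alerts)
#' and normalized to sum to 1 across the evaluable rules, so one plan
#' member yields on average about one evaluable co-prescription episode.
#' The five education-only rules each get `education_rate`.
#'
#' @param education_rate Rate for each education-only rule.
#' @return Named numeric vector over all 18 rule ids.
#' @export
default_co_rx_rates <- function(education_rate = 0.04) {
  counts <- c(warfarin_statins = 939, statins_azoles = 247,
              warfarin_fibrates = 303, simvastatin_amiodarone = 169,
              statins_macrolides = 140, benzodiazepines_azoles = 86,
              warfarin_azoles = 62, ciprofloxacin_tizanidine = 24,
              isotretinoin_tetracyclines = 15, amiodarone_macrolides = 11,
              theophylline_quinolones = 12, amiodarone_quinolones = 7,
              carbamazepine_macrolides = 4)
  education <- setNames(rep(education_rate, 5),
                        c("amiodarone_sotalol", "ergotamines_triptans",
                          "nitrates_pde5_inhibitors", "warfarin_amiodarone",
                          "warfarin_thyroid"))
  c(counts / sum(counts), education)
}

#' Default per-rule baseline change probabilities
#'
#' Control-arm 90-day change rates of the programme's published comparison
#' table, used as calibration for the no-intervention switch propensity
#' (the true counterfactual rates are unknowable from the publication).
#'
#' @return Named numeric vector over the 13 evaluable rule ids.
#' @export
default_baseline_change_probs <- function() {
  c(warfarin_statins = 10 / 939, statins_azoles = 2 / 247,
    warfarin_fibrates = 48 / 303, simvastatin_amiodarone = 3 / 169,
    statins_macrolides = 42 / 140, benzodiazepines_azoles = 4 / 86,
    warfarin_azoles = 1 / 62, ciprofloxacin_tizanidine = 11 / 24,
    isotretinoin_tetracyclines = 1 / 15, amiodarone_macrolides = 4 / 11,
    theophylline_quinolones = 2 / 12, amiodarone_quinolones = 2 / 7,
    carbamazepine_macrolides = 2 / 4)
}

# Bernoulli change indicator on the odds scale: the single planting routine
# used by both the full population generator and the event-level generator,
# so the logistic stage's estimand is recoverable by construction.
plant_change_odds <- function(baseline, odds_ratio, alerted) {
  p <- plogis(qlogis(baseline) + log(odds_ratio) * as.numeric(alerted))
  rbinom(length(p), 1L, p) == 1L
}

# subtract k whole years from a date, clamping Feb 29 to Feb 28
shift_years <- function(date, k) {
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L - k
  out <- as.Date(sprintf("%d-%02d-%02d", y, lt$mon + 1L, lt$mday))
  bad <- is.na(out)
  if (any(bad)) {
    out[bad] <- as.Date(sprintf("%d-%02d-28", y[bad], lt$mon[bad] + 1L))
  }
  out
}

# uniform birth date such that completed age at `ref` is exactly `age`
random_birth_date <- function(age, ref) {
  upper <- shift_years(ref, age)        # birthday falls on ref: age complete
  lower <- shift_years(ref, age + 1L) + 1L
  lower + floor(runif(length(age)) * as.numeric(upper - lower + 1L))
}

#' Simulate a pharmacy-claims population with known ground truth
#'
#' Generates patients, prescribers, and dispensing claims for an
#' alert-enabled plan ("A") and a control-pool plan ("B") so that every
#' downstream stage — detection, alerting, matching, outcome
#' ascertainment, inference — is exercised end-to-end without real data.
#'
#' For each plan member and rule, a co-prescription episode is drawn with
#' the configured rate: two claims with overlapping supply windows from
#' distinct prescribers, the second fill at or after the first (strictly
#' after in ~95% of episodes). A change to a recommended alternative is
#' planted within 90 days of the index fill with probability
#' `plogis(qlogis(baseline) + alerted * log(odds_ratio))`, where `alerted`
#' is true for plan-A events of alert-enabled rule/LOB combinations.
#' Education-only rules generate co-prescriptions (hence alerts) but no
#' outcome. Background dispensings at `noise_rate` per patient-year
#' exercise detection filtering and the comorbidity-proxy lookup; a small
#' fraction of them is reversed.
#'
#' @param config A [sim_config()].
#' @param bank A rulebank; default the built-in one.
#' @return List with `data` (a `claims_data` object) and `ground_truth`
#'   (tibble, one row per generated co-prescription episode, with the
#'   latent arm, alert flag, change probability, and planted change —
#'   consumed only by tests, never by the pipeline).
#' @export
simulate_population <- function(config = sim_config(), bank = load_rulebank()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_population_impl(config, bank))
}

simulate_population_impl <- function(cfg, bank) {
  dict <- bank$drugs
  maintenance <- setNames(dict$maintenance, dict$drug_id)
  rules <- bank$rules

  # ---- patient frame, both plans ----
  n_a <- c(commercial = cfg$n_patients_commercial, medicaid = cfg$n_patients_medicaid)
  n_b <- round(n_a * cfg$control_pool_multiplier)
  pat <- tibble::tibble(
    plan = rep(c("A", "B"), times = c(sum(n_a), sum(n_b))),
    lob = c(rep(names(n_a), n_a), rep(names(n_b), n_b))
  )
  n_pat <- nrow(pat)
  if (n_pat == 0L) {
    abort("sim_config yields zero patients", class = "pddialert_config_error")
  }
  pat$patient_id <- sprintf("P%06d", seq_len(n_pat))
  strata <- sample(names(cfg$age_mix), n_pat, replace = TRUE, prob = cfg$age_mix)
  age_lo <- c(under_18 = 2L, age_18_39 = 18L, age_40_64 = 40L, age_65_plus = 65L)
  age_hi <- c(under_18 = 17L, age_18_39 = 39L, age_40_64 = 64L, age_65_plus = 94L)
  ages <- age_lo[strata] + floor(runif(n_pat) * (age_hi[strata] - age_lo[strata] + 1L))
  pat$birth_date <- random_birth_date(as.integer(ages), cfg$study_start)
  pat$gender <- ifelse(runif(n_pat) < cfg$female_frac, "F", "M")
  pat$eligibility_start <- cfg$study_start - 365L
  pat$eligibility_end <- cfg$study_end + 365L   # provisional; truncated below

  # ---- prescriber pool ----
  n_rx <- cfg$n_prescribers
  pcp <- runif(n_rx) < cfg$primary_care_frac
  pcp_spec <- c("internal medicine", "general practice", "family practice")
  other_spec <- c("cardiology", "dermatology", "psychiatry", "endocrinology",
                  "neurology", "infectious disease", "pulmonology")
  prescribers <- tibble::tibble(
    prescriber_id = sprintf("D%04d", seq_len(n_rx)),
    practitioner_type = sample(names(cfg$prescriber_mix), n_rx, replace = TRUE,
                               prob = cfg$prescriber_mix),
    primary_specialty = ifelse(pcp,
                               sample(pcp_spec, n_rx, replace = TRUE),
                               sample(other_spec, n_rx, replace = TRUE))
  )

  # ---- co-prescription episodes ----
  gt <- list()
  for (rid in names(cfg$co_rx_rate)) {
    rate <- cfg$co_rx_rate[[rid]]
    if (rate <= 0 || is.null(rules[[rid]])) next
    hit <- runif(n_pat) < rate
    if (cfg$suppress_medicaid_benzo_azole &&
        "medicaid" %in% rules[[rid]]$plan_exclusions) {
      hit <- hit & pat$lob != "medicaid"
    }
    if (!any(hit)) next
    idx <- which(hit)
    k <- length(idx)
    rule <- rules[[rid]]
    drug_a <- sample(rule$set_a, k, replace = TRUE)
    drug_b <- sample(rule$set_b, k, replace = TRUE)
    a_first <- runif(k) < 0.5
    gt[[rid]] <- tibble::tibble(
      rule_id = rid, pat_row = idx,
      drug_first = ifelse(a_first, drug_a, drug_b),
      drug_second = ifelse(a_first, drug_b, drug_a)
    )
  }
  gt <- dplyr::bind_rows(gt)
  if (nrow(gt) == 0L) {
    data <- claims_data(pat[, c("patient_id", "birth_date", "gender", "lob",
                                "eligibility_start", "eligibility_end", "plan")],
                        prescribers %>% dplyr::select(-dplyr::any_of("primary_care")),
                        empty_claims())
    return(list(data = data, ground_truth = empty_ground_truth()))
  }
  n_ev <- nrow(gt)
  gt$plan <- pat$plan[gt$pat_row]
  gt$lob <- pat$lob[gt$pat_row]
  gt$patient_id <- pat$patient_id[gt$pat_row]

  supply_for <- function(drug) {
    maint <- maintenance[drug]
    n <- length(drug)
    out <- integer(n)
    out[maint] <- sample(c(30L, 90L), sum(maint), replace = TRUE, prob = c(0.7, 0.3))
    out[!maint] <- 7L + floor(runif(sum(!maint)) * 8)   # 7..14 days
    out
  }
  gt$supply_first <- supply_for(gt$drug_first)
  gt$supply_second <- supply_for(gt$drug_second)
  span <- as.integer(cfg$study_end - cfg$study_start)
  gt$fill_first <- cfg$study_start + floor(runif(n_ev) * span)
  # second fill within the first claim's supply window (ties ~5%)
  max_gap <- pmin(gt$supply_first - 1L,
                  as.integer(cfg$study_end - gt$fill_first))
  tie <- runif(n_ev) < 0.05 | max_gap == 0L
  gap <- ifelse(tie, 0L, 1L + floor(runif(n_ev) * pmax(max_gap, 1L)))
  gt$fill_second <- gt$fill_first + as.integer(gap)
  gt$index_date <- gt$fill_second
  rx1 <- sample(n_rx, n_ev, replace = TRUE)
  rx2 <- ((rx1 - 1L + sample(n_rx - 1L, n_ev, replace = TRUE)) %% n_rx) + 1L
  gt$prescriber_first <- prescribers$prescriber_id[rx1]
  gt$prescriber_second <- prescribers$prescriber_id[rx2]

  # ---- alert arm and planted outcome ----
  gt$arm <- ifelse(gt$plan == "A", "intervention", "control")
  excluded <- vapply(gt$rule_id, function(r) length(rules[[r]]$plan_exclusions) > 0, NA) &
    mapply(function(r, l) l %in% rules[[r]]$plan_exclusions, gt$rule_id, gt$lob)
  gt$alerted <- gt$plan == "A" & !excluded
  evaluable <- vapply(gt$rule_id, function(r) rules[[r]]$evaluable, NA)
  gt$baseline_prob <- ifelse(evaluable,
                             cfg$baseline_change_prob[gt$rule_id], NA_real_)
  gt$p_change <- ifelse(evaluable,
                        plogis(qlogis(gt$baseline_prob) +
                                 log(cfg$intervention_odds_ratio) * gt$alerted),
                        NA_real_)
  gt$change_planted <- FALSE
  gt$change_planted[evaluable] <- plant_change_odds(
    gt$baseline_prob[evaluable], cfg$intervention_odds_ratio, gt$alerted[evaluable])
  gt$change_drug <- NA_character_
  gt$days_to_change <- NA_integer_
  ch <- which(gt$change_planted)
  if (length(ch)) {
    gt$change_drug[ch] <- vapply(ch, function(i) {
      alts <- rule_alternatives(rules[[gt$rule_id[i]]],
                                c(gt$drug_first[i], gt$drug_second[i]))
      sample(alts, 1L)
    }, "")
    gt$days_to_change[ch] <- 1L + floor(runif(length(ch)) * 90)
  }

  # ---- eligibility truncation (fraction with >= 90 days after index) ----
  last_index <- gt %>%
    dplyr::group_by(.data$pat_row) %>%
    dplyr::summarise(last_index = max(.data$index_date), .groups = "drop")
  keep90 <- runif(nrow(last_index)) < cfg$eligible_90d_frac
  elig_end <- dplyr::if_else(
    keep90,
    last_index$last_index + 90L + floor(runif(nrow(last_index)) * 276),
    last_index$last_index + floor(runif(nrow(last_index)) * 90))
  pat$eligibility_end[last_index$pat_row] <- elig_end

  # ---- claims assembly ----
  pair_claims <- tibble::tibble(
    patient_id = rep(gt$patient_id, 2L),
    drug_id = c(gt$drug_first, gt$drug_second),
    fill_date = c(gt$fill_first, gt$fill_second),
    days_supply = c(gt$supply_first, gt$supply_second),
    prescriber_id = c(gt$prescriber_first, gt$prescriber_second),
    lob = rep(gt$lob, 2L),
    reversed = FALSE
  )
  change_claims <- if (length(ch)) {
    tibble::tibble(
      patient_id = gt$patient_id[ch],
      drug_id = gt$change_drug[ch],
      fill_date = gt$index_date[ch] + gt$days_to_change[ch],
      days_supply = supply_for(gt$change_drug[ch]),
      prescriber_id = gt$prescriber_second[ch],
      lob = gt$lob[ch],
      reversed = FALSE
    )
  } else NULL
  noise_pool <- setdiff(dict$drug_id, drugs_in_scope(bank))
  noise_span_days <- as.integer(cfg$study_end + 90L - (cfg$study_start - 180L))
  n_noise <- stats::rpois(n_pat, cfg$noise_rate * noise_span_days / 365.25)
  noise_rows <- rep(seq_len(n_pat), n_noise)
  noise_claims <- if (length(noise_rows)) {
    tibble::tibble(
      patient_id = pat$patient_id[noise_rows],
      drug_id = sample(noise_pool, length(noise_rows), replace = TRUE),
      fill_date = cfg$study_start - 180L +
        floor(runif(length(noise_rows)) * noise_span_days),
      days_supply = 30L,
      prescriber_id = prescribers$prescriber_id[
        sample(n_rx, length(noise_rows), replace = TRUE)],
      lob = pat$lob[noise_rows],
      reversed = runif(length(noise_rows)) < cfg$noise_reversal_rate
    )
  } else NULL
  claims <- dplyr::bind_rows(pair_claims, change_claims, noise_claims) %>%
    dplyr::arrange(.data$patient_id, .data$fill_date, .data$drug_id) %>%
    dplyr::mutate(claim_id = sprintf("C%07d", dplyr::row_number()), .before = 1L)

  gt_out <- gt %>%
    dplyr::mutate(event_key = sprintf("G%05d", dplyr::row_number())) %>%
    dplyr::select("event_key", "rule_id", "patient_id", "plan", "lob", "arm",
                  "alerted", "drug_first", "drug_second", "fill_first",
                  "fill_second", "index_date", "baseline_prob", "p_change",
                  "change_planted", "change_drug", "days_to_change")
  data <- claims_data(
    pat[, c("patient_id", "birth_date", "gender", "lob",
            "eligibility_start", "eligibility_end", "plan")],
    prescribers, claims)
  list(data = data, ground_truth = gt_out)
}

empty_claims <- function() {
  tibble::tibble(claim_id = character(), patient_id = character(),
                 drug_id = character(), fill_date = as.Date(character()),
                 days_supply = integer(), prescriber_id = character(),
                 lob = character(), reversed = logical())
}

empty_ground_truth <- function() {
  tibble::tibble(event_key = character(), rule_id = character(),
                 patient_id = character(), plan = character(), lob = character(),
                 arm = character(), alerted = logical(), drug_first = character(),
                 drug_second = character(), fill_first = as.Date(character()),
                 fill_second = as.Date(character()), index_date = as.Date(character()),
                 baseline_prob = double(), p_change = double(),
                 change_planted = logical(), change_drug = character(),
                 days_to_change = integer())
}

#' Write a simulated population to a directory
#'
#' Writes `patients.csv`, `prescribers.csv`, `claims.csv`, and
#' `ground_truth.csv`.
#'
#' @param sim Result of [simulate_population()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_claims(sim$data, dir)
  readr::write_csv(sim$ground_truth, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Simulate matched outcome records directly
#'
#' Event-level shortcut around the full claims generator for studying the
#' inference stage: generates `n_per_arm` intervention and `n_per_arm`
#' control outcome records whose binary change indicator is planted by the
#' same odds-scale routine the population generator uses, together with
#' independently drawn covariates (gender, age group, practitioner type,
#' severity, acute-medication flag, and comorbidity-proxy indicators) that
#' carry no effect of their own. Useful for parameter-recovery and
#' operating-characteristic studies where re-running detection and matching
#' would only add noise-free bookkeeping.
#'
#' @param n_per_arm Events per arm.
#' @param baseline Baseline change probability (control arm).
#' @param odds_ratio Intervention effect on the odds scale.
#' @param seed Optional integer seed.
#' @return Tibble with columns `intervention` (0/1), `success` (logical),
#'   and the covariates accepted by [fit_outcome_model()].
#' @export
simulate_matched_outcomes <- function(n_per_arm, baseline, odds_ratio, seed = NULL) {
  run <- function() {
    n <- 2L * n_per_arm
    intervention <- rep(c(1L, 0L), each = n_per_arm)
    rx_categories <- rxrisk_categories()
    out <- tibble::tibble(
      intervention = intervention,
      success = plant_change_odds(rep(baseline, n), odds_ratio, intervention == 1L),
      male = runif(n) < 0.463,
      age_group = sample(c("0-49", "50-64", "65-79", "80+"), n, replace = TRUE,
                         prob = c(0.05, 0.25, 0.5, 0.2)),
      practitioner_type = sample(c("physician", "nurse_practitioner",
                                   "physician_assistant", "other"), n,
                                 replace = TRUE, prob = c(0.872, 0.064, 0.044, 0.02)),
      specialist = runif(n) < 0.35,
      acute_medication = runif(n) < 0.3,
      severity = sample(c("major", "moderate", "minor"), n, replace = TRUE,
                        prob = c(0.5, 0.4, 0.1))
    )
    for (cat in rx_categories) out[[cat]] <- runif(n) < 0.15
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
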