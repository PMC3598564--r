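# Independent oracles and fixture builders used across the suite.

# --- two-sided Fisher by exhaustive enumeration ---------------------------
# Enumerates every table with the observed margins; point probabilities are
# computed from log-factorial products and normalized by their sum (no
# dhyper, no choose(N, c1) shortcut), so the route is independent of the
# package implementation.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  logw <- -(lgamma(support + 1) + lgamma(r1 - support + 1) +
              lgamma(c1 - support + 1) + lgamma(n - r1 - c1 + support + 1))
  w <- exp(logw - max(logw))
  probs <- w / sum(w)
  obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# --- O(n^2) brute-force co-exposure detection -----------------------------
# Naive nested loops over claim pairs per patient and rule; episode merge by
# linear scan. Returns a sorted key string per event for set comparison.
oracle_detect_keys <- function(claims, bank, grace = 0) {
  live <- claims[!claims$reversed, , drop = FALSE]
  live$ws <- as.numeric(live$fill_date)
  live$we <- live$ws + live$days_supply
  keys <- character(0)
  for (rule in bank$rules) {
    for (pid in unique(live$patient_id)) {
      cl <- live[live$patient_id == pid, , drop = FALSE]
      ai <- which(cl$drug_id %in% rule$set_a)
      bi <- which(cl$drug_id %in% rule$set_b)
      if (!length(ai) || !length(bi)) next
      pairs <- NULL
      for (i in ai) for (j in bi) {
        if (cl$ws[i] < cl$we[j] + grace && cl$ws[j] < cl$we[i] + grace) {
          b_second <- cl$fill_date[j] >= cl$fill_date[i]
          pairs <- rbind(pairs, data.frame(
            co_start = max(cl$ws[i], cl$ws[j]),
            co_end = min(cl$we[i], cl$we[j]),
            first = if (b_second) cl$claim_id[i] else cl$claim_id[j],
            second = if (b_second) cl$claim_id[j] else cl$claim_id[i],
            index = if (b_second) cl$fill_date[j] else cl$fill_date[i]))
        }
      }
      if (is.null(pairs)) next
      pairs <- pairs[order(pairs$co_start, pairs$second, pairs$first), , drop = FALSE]
      max_end <- -Inf
      for (k in seq_len(nrow(pairs))) {
        if (pairs$co_start[k] > max_end + grace) {   # new episode
          keys <- c(keys, paste(rule$rule_id, pid, pairs$first[k],
                                pairs$second[k], pairs$index[k], sep = "|"))
        }
        max_end <- max(max_end, pairs$co_end[k])
      }
    }
  }
  sort(keys)
}

event_keys <- function(events) {
  sort(paste(events$rule_id, events$patient_id, events$first_claim_id,
             events$second_claim_id, events$index_date, sep = "|"))
}

# --- exact maximum bipartite matching (augmenting paths) ------------------
# compat: logical matrix cases x controls. Returns the maximum number of
# disjoint case-control pairs.
oracle_max_matching <- function(compat) {
  n_case <- nrow(compat); n_ctrl <- ncol(compat)
  if (n_case == 0L || n_ctrl == 0L) return(0L)
  match_of <- rep(0L, n_ctrl)   # control j -> case currently holding it
  total <- 0L
  for (i in seq_len(n_case)) {
    seen <- rep(FALSE, n_ctrl)
    aug <- function(u) {
      for (j in which(compat[u, ])) {
        if (!seen[j]) {
          seen[j] <<- TRUE
          if (match_of[j] == 0L || aug(match_of[j])) {
            match_of[j] <<- u
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (aug(i)) total <- total + 1L
  }
  total
}

# --- fixture builders -----------------------------------------------------
mk_patients <- function(n, lob = "commercial", plan = "A",
                        birth = as.Date("1945-06-15"), gender = "F",
                        elig_start = as.Date("2009-01-01"),
                        elig_end = as.Date("2012-01-01"), ids = NULL) {
  tibble::tibble(
    patient_id = ids %||% sprintf("P%03d", seq_len(n)),
    birth_date = rep(as.Date(birth), length.out = n),
    gender = rep(gender, length.out = n),
    lob = rep(lob, length.out = n),
    eligibility_start = rep(as.Date(elig_start), length.out = n),
    eligibility_end = rep(as.Date(elig_end), length.out = n),
    plan = rep(plan, length.out = n))
}

mk_prescribers <- function(n, type = "physician", specialty = "cardiology") {
  tibble::tibble(prescriber_id = sprintf("D%03d", seq_len(n)),
                 practitioner_type = rep(type, length.out = n),
                 primary_specialty = rep(specialty, length.out = n))
}

mk_claims <- function(patient_id, drug_id, fill_date, days_supply = 30L,
                      prescriber_id = "D001", lob = "commercial",
                      reversed = FALSE) {
  n <- max(lengths(list(patient_id, drug_id, fill_date)))
  tibble::tibble(
    claim_id = sprintf("C%03d", seq_len(n)),
    patient_id = rep(patient_id, length.out = n),
    drug_id = rep(drug_id, length.out = n),
    fill_date = rep(as.Date(fill_date), length.out = n),
    days_supply = rep(as.integer(days_supply), length.out = n),
    prescriber_id = rep(prescriber_id, length.out = n),
    lob = rep(lob, length.out = n),
    reversed = rep(reversed, length.out = n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Reduced two-rule bank written and loaded through the public reader so
# fixtures exercise the same validation path as the shipped bank.
tiny_bank <- function() {
  path <- tempfile(fileext = ".yaml")
  writeLines('
rules:
  - rule_id: warfarin_fibrates
    display_name: "Warfarin + Fibrates"
    set_a: [warfarin]
    set_b: [fenofibrate, gemfibrozil]
    severity: moderate
    evaluable: true
    plan_exclusions: []
    strategies:
      - {kind: change_alternative, text: "change lipid therapy"}
    alternatives:
      fenofibrate: [pravastatin, ezetimibe]
      gemfibrozil: [pravastatin, ezetimibe]
  - rule_id: benzodiazepines_azoles
    display_name: "Benzodiazepines + Azoles"
    set_a: [alprazolam]
    set_b: [fluconazole]
    severity: major
    evaluable: true
    plan_exclusions: [medicaid]
    strategies:
      - {kind: change_alternative, text: "change benzodiazepine"}
    alternatives:
      alprazolam: [lorazepam, temazepam]
      fluconazole: [terbinafine]
drugs:
  - {drug_id: warfarin, generic_name: warfarin, class_tags: [anticoagulant], maintenance: true}
  - {drug_id: fenofibrate, generic_name: fenofibrate, class_tags: [fibrate], maintenance: true}
  - {drug_id: gemfibrozil, generic_name: gemfibrozil, class_tags: [fibrate], maintenance: true}
  - {drug_id: pravastatin, generic_name: pravastatin, class_tags: [statin], maintenance: true}
  - {drug_id: ezetimibe, generic_name: ezetimibe, class_tags: [cholesterol_absorption_inhibitor], maintenance: true}
  - {drug_id: alprazolam, generic_name: alprazolam, class_tags: [benzodiazepine], maintenance: true}
  - {drug_id: fluconazole, generic_name: fluconazole, class_tags: [azole_antifungal], maintenance: false}
  - {drug_id: lorazepam, generic_name: lorazepam, class_tags: [benzodiazepine], maintenance: true}
  - {drug_id: temazepam, generic_name: temazepam, class_tags: [benzodiazepine], maintenance: true}
  - {drug_id: terbinafine, generic_name: terbinafine, class_tags: [allylamine_antifungal], maintenance: false}
', path)
  load_rulebank(path)
}

# Random claims population over the full bank's drugs, for property tests.
random_population <- function(n_patients, n_claims, bank, seed,
                              reversed_rate = 0.05, birth_span = 20000) {
  withr::with_seed(seed, {
    drugs <- c(drugs_in_scope(bank),
               sample(setdiff(bank$drugs$drug_id, drugs_in_scope(bank)), 5))
    pats <- mk_patients(n_patients,
                        lob = sample(c("commercial", "medicaid"), n_patients,
                                     replace = TRUE),
                        plan = sample(c("A", "B"), n_patients, replace = TRUE),
                        gender = sample(c("F", "M"), n_patients, replace = TRUE),
                        birth = as.Date("1940-01-01") +
                          floor(runif(n_patients) * birth_span))
    claims <- tibble::tibble(
      claim_id = sprintf("C%05d", seq_len(n_claims)),
      patient_id = sample(pats$patient_id, n_claims, replace = TRUE),
      drug_id = sample(drugs, n_claims, replace = TRUE),
      fill_date = as.Date("2010-05-01") + floor(runif(n_claims) * 180),
      days_supply = sample(c(7L, 14L, 30L, 90L), n_claims, replace = TRUE),
      prescriber_id = sample(sprintf("D%03d", 1:20), n_claims, replace = TRUE),
      reversed = runif(n_claims) < reversed_rate)
    claims$lob <- pats$lob[match(claims$patient_id, pats$patient_id)]
    claims_data(pats, mk_prescribers(20), claims)
  })
}
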