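tab <- function(a, b, c, d) matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)

test_that("test selection follows the minimum expected cell count rule", {
  # expected counts computed by hand: outer(rowSums, colSums)/N
  t1 <- tab(8, 4, 2, 10)      # min expected = 12*10/24 = 5.0 -> Fisher
  expect_equal(min(outer(rowSums(t1), colSums(t1)) / sum(t1)), 5)
  expect_equal(choose_test(t1), "fisher_exact")
  t2 <- tab(8, 161, 3, 166)   # min expected = 169*11/338 = 5.5 -> chi-square
  expect_equal(min(outer(rowSums(t2), colSums(t2)) / sum(t2)), 5.5)
  expect_equal(choose_test(t2), "chi_square")
  t3 <- tab(55, 248, 48, 255) # min expected 51.5 -> chi-square
  expect_equal(choose_test(t3), "chi_square")
  # zero margin forces Fisher
  expect_equal(choose_test(tab(0, 10, 0, 12)), "fisher_exact")
  expect_error(choose_test(tab(0, 0, 0, 0)), class = "pddialert_data_error")
  expect_error(choose_test(matrix(1:6, 2)), class = "pddialert_data_error")
})

test_that("two-sided Fisher equals enumeration and the reference implementation", {
  cases <- list(tab(8, 4, 2, 10), tab(2, 9, 4, 7), tab(1, 61, 1, 61),
                tab(0, 5, 3, 2), tab(13, 11, 11, 13), tab(2, 2, 2, 2))
  for (t in cases) {
    expect_equal(fisher_exact_p(t), oracle_fisher_p(t), tolerance = 1e-12)
    expect_equal(fisher_exact_p(t), fisher.test(t)$p.value, tolerance = 1e-9)
  }
  # random spot checks against stats::fisher.test
  for (s in 1:50) {
    t <- withr::with_seed(s, matrix(rpois(4, 8), 2))
    if (sum(t) == 0) next
    expect_equal(fisher_exact_p(t), fisher.test(t)$p.value, tolerance = 1e-9,
                 label = sprintf("seed %d", s))
  }
})

test_that("chi-square branch is uncorrected Pearson with df = 1", {
  t <- tab(154, 1865, 132, 1887)
  cmp <- compare_arms(t)
  expect_equal(cmp$test_used, "chi_square")
  expect_equal(cmp$p_value, 0.177, tolerance = 2e-3)  # printed to 3 d.p.
  # invariant under arm swap and transposition
  expect_equal(compare_arms(t[2:1, ])$p_value, cmp$p_value)
  expect_equal(compare_arms(t(t))$p_value, cmp$p_value)
  # symmetric table has no association
  expect_equal(compare_arms(tab(5, 20, 5, 20))$p_value, 1)
  expect_equal(compare_arms(tab(2, 2, 2, 2))$p_value, 1)
})

test_that("per-rule inference reproduces the published comparison table", {
  counts <- published_change_counts()
  res <- pair_results_from_counts(counts)
  # agreement at the printed precision (last digit rounded or truncated)
  agrees <- function(p, printed) {
    digits <- nchar(sub("^[01]\\.?", "", as.character(printed)))
    round(p, digits) == printed || floor(p * 10^digits) / 10^digits == printed
  }
  for (i in seq_len(nrow(res))) {
    expect_true(agrees(res$p_value[i], res$published_p[i]),
                label = sprintf("%s: computed %.4f vs published %s",
                                res$rule_id[i], res$p_value[i],
                                res$published_p[i]))
  }
  # the discriminating test choices
  tu <- setNames(res$test_used, res$rule_id)
  expect_equal(tu[["theophylline_quinolones"]], "fisher_exact")
  expect_equal(tu[["amiodarone_macrolides"]], "fisher_exact")
  expect_equal(tu[["simvastatin_amiodarone"]], "chi_square")
  expect_equal(tu[["total"]], "chi_square")
})

test_that("logistic stage recovers a planted intervention odds ratio", {
  fits <- lapply(1:10, function(s) {
    rec <- simulate_matched_outcomes(5000, baseline = 0.07, odds_ratio = 1.5,
                                     seed = 12000 + s)
    fit_outcome_model(rec)
  })
  rows <- dplyr::bind_rows(lapply(fits, function(f) {
    f$tidy[f$tidy$term == "intervention", ]
  }))
  # a Wald 95% CI misses the truth in ~1 replicate of 10 at most usually
  expect_gte(sum(rows$or_lower <= 1.5 & 1.5 <= rows$or_upper), 8L)
  expect_equal(mean(rows$odds_ratio), 1.5, tolerance = 0.1)
  expect_equal(unname(rows$odds_ratio), unname(exp(rows$estimate)))
  # reference levels carry no coefficient rows
  expect_false(any(grepl("physician$|65-79|severitymoderate", fits[[1]]$tidy$term)))
})

test_that("degenerate outcomes and missing columns raise errors", {
  rec <- simulate_matched_outcomes(50, 0.1, 1, seed = 1L)
  rec$success <- FALSE
  expect_error(fit_outcome_model(rec), class = "pddialert_model_error")
  expect_error(fit_outcome_model(tibble::tibble(success = c(TRUE, FALSE))),
               class = "pddialert_data_error")
})

test_that("intervention p-values are uniform under a permuted null", {
  pvals <- vapply(1:60, function(s) {
    rec <- simulate_matched_outcomes(400, baseline = 0.2, odds_ratio = 1.4,
                                     seed = 9000 + s)
    rec$intervention <- withr::with_seed(s, sample(rec$intervention))
    fit <- fit_outcome_model(rec[, c("intervention", "success")])
    fit$tidy$p_value[fit$tidy$term == "intervention"]
  }, 0)
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("comorbidity flags come from the lookback window and are monotone", {
  bank <- load_rulebank()
  idx <- tibble::tibble(patient_id = c("P001", "P002"),
                        index_date = as.Date("2010-06-01"))
  pats <- mk_patients(2)
  claims <- dplyr::bind_rows(
    mk_claims("P001", "sertraline", "2010-03-01"),        # in window
    mk_claims("P001", "metformin", "2009-06-01"),         # too old
    mk_claims("P002", "albuterol", "2010-06-01"))         # on index day
  claims$claim_id <- sprintf("C%03d", seq_len(nrow(claims)))
  flags <- assign_rxrisk(idx, claims, bank)
  expect_true(flags$depression[flags$patient_id == "P001"])
  expect_false(flags$diabetes[flags$patient_id == "P001"])
  expect_true(flags$asthma[flags$patient_id == "P002"])
  expect_false(flags$depression[flags$patient_id == "P002"])
  # no claims -> all flags false
  none <- assign_rxrisk(tibble::tibble(patient_id = "P009",
                                       index_date = as.Date("2010-06-01")),
                        claims[0, ], bank)
  expect_false(any(unlist(none[rxrisk_categories()])))
  # monotone: adding a claim can only set flags
  more <- dplyr::bind_rows(claims, mk_claims("P001", "metformin", "2010-05-01"))
  more$claim_id <- sprintf("C%03d", seq_len(nrow(more)))
  flags2 <- assign_rxrisk(idx, more, bank)
  for (cat in rxrisk_categories()) {
    expect_true(all(flags2[[cat]] >= flags[[cat]]))
  }
})

test_that("the benzodiazepine drugs map to the anxiety category", {
  bank <- load_rulebank()
  map <- load_rxrisk_map()
  expect_equal(nrow(map), 12L)
  idx <- tibble::tibble(patient_id = "P001", index_date = as.Date("2010-06-01"))
  flags <- assign_rxrisk(idx, mk_claims("P001", "lorazepam", "2010-05-20"),
                         bank)
  expect_true(flags$anxiety_tension)
})
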