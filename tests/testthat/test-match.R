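# minimal event builder for matcher tests
mk_events <- function(ids, patient_ids, rule = "warfarin_fibrates",
                      index = "2010-05-15", lob = "commercial") {
  tibble::tibble(event_id = ids, rule_id = rule, patient_id = patient_ids,
                 index_date = as.Date(rep(index, length.out = length(ids))),
                 lob = rep(lob, length.out = length(ids)))
}

test_that("a compatible control within two years of age is matched", {
  pats <- dplyr::bind_rows(
    mk_patients(1, ids = "CASE1", birth = "1940-03-01"),
    mk_patients(1, ids = "CTRL1", birth = "1938-06-01", plan = "B"))
  m <- match_cohorts(mk_events("E1", "CASE1"), mk_events("E2", "CTRL1"), pats)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$age_gap, 1L)   # ages 71 vs 70 at the May index
  expect_equal(nrow(m$unmatched), 0L)
})

test_that("age gap above two years, or any stratum mismatch, blocks the match", {
  base_case <- mk_events("E1", "CASE1")
  mk2 <- function(ctrl_birth = "1940-03-01", ctrl_gender = "F",
                  ctrl_lob = "commercial", ctrl_index = "2010-05-20",
                  case_gender = "F") {
    pats <- dplyr::bind_rows(
      mk_patients(1, ids = "CASE1", birth = "1940-03-01", gender = case_gender),
      mk_patients(1, ids = "CTRL1", birth = ctrl_birth, gender = ctrl_gender,
                  plan = "B"))
    match_cohorts(base_case,
                  mk_events("E2", "CTRL1", index = ctrl_index, lob = ctrl_lob),
                  pats)
  }
  expect_equal(nrow(mk2(ctrl_birth = "1943-04-01")$pairs), 0L)  # 3 years apart
  expect_equal(nrow(mk2(ctrl_gender = "M")$pairs), 0L)
  expect_equal(nrow(mk2(ctrl_lob = "medicaid")$pairs), 0L)
  expect_equal(nrow(mk2(ctrl_index = "2010-06-20")$pairs), 0L)  # other month
  expect_equal(nrow(mk2()$pairs), 1L)
})

test_that("empty control pool leaves every intervention unmatched, with warning", {
  pats <- mk_patients(1, ids = "CASE1")
  expect_warning(
    m <- match_cohorts(mk_events("E1", "CASE1"), mk_events(character(), character()),
                       pats),
    "empty control pool")
  expect_equal(nrow(m$pairs), 0L)
  expect_equal(nrow(m$unmatched), 1L)
})

test_that("a control patient is used in at most one cohort across rules", {
  pats <- dplyr::bind_rows(
    mk_patients(2, ids = c("CASE1", "CASE2"), birth = "1940-01-01"),
    mk_patients(1, ids = "CTRL1", birth = "1940-06-01", plan = "B"))
  cases <- dplyr::bind_rows(
    mk_events("E1", "CASE1", rule = "warfarin_fibrates"),
    mk_events("E2", "CASE2", rule = "benzodiazepines_azoles"))
  ctrls <- dplyr::bind_rows(
    mk_events("E3", "CTRL1", rule = "warfarin_fibrates"),
    mk_events("E4", "CTRL1", rule = "benzodiazepines_azoles"))
  m <- match_cohorts(cases, ctrls, pats)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(nrow(m$unmatched), 1L)
  # while an intervention patient may appear in several cohorts
  cases2 <- dplyr::bind_rows(
    mk_events("E1", "CASE1", rule = "warfarin_fibrates"),
    mk_events("E2", "CASE1", rule = "benzodiazepines_azoles"))
  ctrls2 <- dplyr::bind_rows(
    mk_events("E3", "CTRL1", rule = "warfarin_fibrates"),
    mk_events("E4", "CTRL2", rule = "benzodiazepines_azoles"))
  pats2 <- dplyr::bind_rows(
    mk_patients(1, ids = "CASE1", birth = "1940-01-01"),
    mk_patients(2, ids = c("CTRL1", "CTRL2"), birth = "1940-06-01", plan = "B"))
  m2 <- match_cohorts(cases2, ctrls2, pats2)
  expect_equal(nrow(m2$pairs), 2L)
})

test_that("greedy nearest-age-first attains the optimum on sorted fixtures", {
  # cases at ages 70, 71, 72; controls at 70, 72, 74: optimal = 3 pairs
  pats <- dplyr::bind_rows(
    mk_patients(3, ids = c("A1", "A2", "A3"),
                birth = as.Date(c("1940-05-15", "1939-05-15", "1938-05-15"))),
    mk_patients(3, ids = c("B1", "B2", "B3"), plan = "B",
                birth = as.Date(c("1940-05-15", "1938-05-15", "1936-05-15"))))
  cases <- mk_events(c("E1", "E2", "E3"), c("A1", "A2", "A3"))
  ctrls <- mk_events(c("E4", "E5", "E6"), c("B1", "B2", "B3"))
  m <- match_cohorts(cases, ctrls, pats)
  ages_case <- c(70L, 71L, 72L)
  ages_ctrl <- c(70L, 72L, 74L)
  compat <- abs(outer(ages_case, ages_ctrl, `-`)) <= 2L
  expect_equal(nrow(m$pairs), oracle_max_matching(compat))
})

test_that("greedy pair count never exceeds the exhaustive maximum matching", {
  for (s in 1:20) {
    n_case <- withr::with_seed(s, sample(3:10, 1))
    n_ctrl <- withr::with_seed(s + 100, sample(3:10, 1))
    ages_case <- withr::with_seed(s + 200, sample(60:80, n_case, replace = TRUE))
    ages_ctrl <- withr::with_seed(s + 300, sample(60:80, n_ctrl, replace = TRUE))
    births_case <- as.Date("2010-05-15") - round(ages_case * 365.25 + 100)
    births_ctrl <- as.Date("2010-05-15") - round(ages_ctrl * 365.25 + 100)
    pats <- dplyr::bind_rows(
      mk_patients(n_case, ids = sprintf("A%02d", 1:n_case), birth = births_case),
      mk_patients(n_ctrl, ids = sprintf("B%02d", 1:n_ctrl), birth = births_ctrl,
                  plan = "B"))
    cases <- mk_events(sprintf("E%02d", 1:n_case), sprintf("A%02d", 1:n_case))
    ctrls <- mk_events(sprintf("F%02d", 1:n_ctrl), sprintf("B%02d", 1:n_ctrl))
    m <- match_cohorts(cases, ctrls, pats)
    age_c <- age_at(births_case, as.Date("2010-05-15"))
    age_k <- age_at(births_ctrl, as.Date("2010-05-15"))
    compat <- abs(outer(age_c, age_k, `-`)) <= 2L
    optimum <- oracle_max_matching(compat)
    expect_lte(nrow(m$pairs), optimum)
    # nearest-age greedy should not be badly suboptimal on these fixtures
    expect_gte(nrow(m$pairs), optimum - 1L)
  }
})

test_that("cohort summary counts per rule and totals correctly", {
  counts <- published_change_counts()
  per_rule <- counts[counts$rule_id != "total", ]
  pairs <- tibble::tibble(
    pair_id = sprintf("M%04d", seq_len(sum(per_rule$n_per_arm))),
    rule_id = rep(per_rule$rule_id, per_rule$n_per_arm))
  cs <- cohort_summary(pairs)
  expect_equal(cs$n_pairs[cs$rule_id == "total"], 2019L)
  expect_equal(cs$n_pairs[cs$rule_id == "warfarin_statins"], 939L)
  expect_equal(sum(cs$pct_of_total[cs$rule_id != "total"]), 100,
               tolerance = 1e-9)
  empty <- cohort_summary(tibble::tibble(pair_id = character(),
                                         rule_id = character()))
  expect_equal(empty$n_pairs, 0L)
})
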