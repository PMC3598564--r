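bank2 <- tiny_bank()

# one matched pair fixture on the warfarin-fibrate rule; extra claims are
# appended per test to probe the ascertainment window
outcome_fixture <- function(extra_claims = NULL) {
  pats <- dplyr::bind_rows(
    mk_patients(1, ids = "CASE1", birth = "1940-03-01"),
    mk_patients(1, ids = "CTRL1", birth = "1940-06-01", plan = "B"))
  base <- mk_claims(c("CASE1", "CASE1", "CTRL1", "CTRL1"),
                    c("warfarin", "gemfibrozil", "warfarin", "gemfibrozil"),
                    c("2010-05-01", "2010-05-10", "2010-05-03", "2010-05-12"))
  claims <- dplyr::bind_rows(base, extra_claims)
  claims$claim_id <- sprintf("C%03d", seq_len(nrow(claims)))
  data <- claims_data(pats, mk_prescribers(1), claims)
  events <- detect_events(data, bank2)
  pairs <- match_cohorts(events[events$patient_id == "CASE1", ],
                         events[events$patient_id == "CTRL1", ], pats)$pairs
  list(data = data, events = events, pairs = pairs)
}

chg <- function(patient, drug, date) {
  mk_claims(patient, drug, date)
}

test_that("an alternative filled in-window is a success with correct latency", {
  fx <- outcome_fixture(chg("CASE1", "ezetimibe", "2010-06-09"))  # index+30
  rec <- ascertain_changes(fx$pairs, fx$events, fx$data, bank2)
  expect_equal(nrow(rec), 2L)
  case <- rec[rec$arm == "intervention", ]
  expect_true(case$success)
  expect_equal(case$change_drug_id, "ezetimibe")
  expect_equal(case$days_to_change, 30L)
  expect_false(rec$success[rec$arm == "control"])
})

test_that("window boundaries: day 0 excluded, day 90 included, day 91 excluded", {
  # case index date is 2010-05-10
  on_index <- outcome_fixture(chg("CASE1", "ezetimibe", "2010-05-10"))
  expect_false(ascertain_changes(on_index$pairs, on_index$events, on_index$data,
                                 bank2)$success[1])
  day90 <- outcome_fixture(chg("CASE1", "ezetimibe", "2010-08-08"))
  r90 <- ascertain_changes(day90$pairs, day90$events, day90$data, bank2)
  expect_true(r90$success[r90$arm == "intervention"])
  expect_equal(r90$days_to_change[r90$arm == "intervention"], 90L)
  day91 <- outcome_fixture(chg("CASE1", "ezetimibe", "2010-08-09"))
  r91 <- ascertain_changes(day91$pairs, day91$events, day91$data, bank2)
  expect_false(r91$success[r91$arm == "intervention"])
  before <- outcome_fixture(chg("CASE1", "ezetimibe", "2010-05-05"))  # index-5
  expect_false(ascertain_changes(before$pairs, before$events, before$data,
                                 bank2)$success[1])
})

test_that("refills of the interacting drugs never count as changes", {
  fx <- outcome_fixture(chg("CASE1", c("warfarin", "gemfibrozil"),
                            c("2010-06-01", "2010-06-05")))
  rec <- ascertain_changes(fx$pairs, fx$events, fx$data, bank2)
  expect_false(any(rec$success))
})

test_that("reversed alternative claims never count", {
  extra <- chg("CASE1", "ezetimibe", "2010-06-09")
  extra$reversed <- TRUE
  fx <- outcome_fixture(extra)
  expect_false(any(ascertain_changes(fx$pairs, fx$events, fx$data, bank2)$success))
})

test_that("both arms are ascertained against their own index dates", {
  # control index is 2010-05-12; a control fill at its day 90 qualifies
  fx <- outcome_fixture(chg("CTRL1", "pravastatin", "2010-08-10"))
  rec <- ascertain_changes(fx$pairs, fx$events, fx$data, bank2)
  ctrl <- rec[rec$arm == "control", ]
  expect_true(ctrl$success)
  expect_equal(ctrl$days_to_change, 90L)
})

test_that("strict-switch mode requires the interacting drugs not be refilled", {
  extra <- dplyr::bind_rows(chg("CASE1", "ezetimibe", "2010-06-09"),
                            chg("CASE1", "gemfibrozil", "2010-07-01"))
  fx <- outcome_fixture(extra)
  expect_true(ascertain_changes(fx$pairs, fx$events, fx$data, bank2)$success[1])
  expect_false(ascertain_changes(fx$pairs, fx$events, fx$data, bank2,
                                 strict_switch = TRUE)$success[1])
})

test_that("incident-alternative mode ignores alternatives already on board", {
  extra <- dplyr::bind_rows(chg("CASE1", "ezetimibe", "2010-03-01"),  # prior use
                            chg("CASE1", "ezetimibe", "2010-06-09"))
  fx <- outcome_fixture(extra)
  expect_true(ascertain_changes(fx$pairs, fx$events, fx$data, bank2)$success[1])
  expect_false(ascertain_changes(fx$pairs, fx$events, fx$data, bank2,
                                 incident_alternative = TRUE)$success[1])
})

test_that("education-only rules cannot be ascertained", {
  bank <- load_rulebank()
  pairs <- tibble::tibble(pair_id = "M1", rule_id = "warfarin_amiodarone",
                          intervention_event_id = "E1", control_event_id = "E2",
                          intervention_patient_id = "P001",
                          control_patient_id = "P002",
                          intervention_index = as.Date("2010-05-10"),
                          control_index = as.Date("2010-05-10"))
  events <- tibble::tibble(event_id = c("E1", "E2"),
                           first_drug_id = "warfarin",
                           second_drug_id = "amiodarone")
  claims <- mk_claims("P001", "warfarin", "2010-05-01")
  expect_error(ascertain_changes(pairs, events, claims, bank),
               class = "pddialert_data_error")
})

test_that("change breakdown counts planted switches and conserves totals", {
  # plant the published benzodiazepine-azole switch pattern: 8 lorazepam,
  # 2 temazepam, 1 terbinafine
  n <- 11
  pats <- dplyr::bind_rows(
    mk_patients(n, ids = sprintf("CASE%02d", 1:n), birth = "1950-01-01"),
    mk_patients(n, ids = sprintf("CTRL%02d", 1:n), birth = "1950-06-01",
                plan = "B"))
  two_claims <- function(ids) {
    dplyr::bind_rows(mk_claims(ids, "alprazolam", "2010-05-01"),
                     mk_claims(ids, "fluconazole", "2010-05-05"))
  }
  switch_drug <- rep(c("lorazepam", "temazepam", "terbinafine"), c(8, 2, 1))
  claims <- dplyr::bind_rows(
    two_claims(sprintf("CASE%02d", 1:n)),
    two_claims(sprintf("CTRL%02d", 1:n)),
    mk_claims(sprintf("CASE%02d", 1:n), switch_drug, "2010-06-01"))
  claims$claim_id <- sprintf("C%04d", seq_len(nrow(claims)))
  data <- claims_data(pats, mk_prescribers(1), claims)
  events <- detect_events(data, bank2)
  m <- match_cohorts(events[grepl("CASE", events$patient_id), ],
                     events[grepl("CTRL", events$patient_id), ], pats)
  expect_equal(nrow(m$pairs), n)
  rec <- ascertain_changes(m$pairs, events, data, bank2)
  bd <- change_breakdown(rec)
  expect_equal(bd$n[bd$change_drug_id == "lorazepam"], 8L)
  expect_equal(bd$n[bd$change_drug_id == "temazepam"], 2L)
  expect_equal(bd$n[bd$change_drug_id == "terbinafine"], 1L)
  # conservation: breakdown sums equal success totals per rule and overall
  expect_equal(sum(bd$n), sum(rec$success))
  per_rule <- dplyr::count(dplyr::filter(rec, success), rule_id)
  agg <- dplyr::summarise(dplyr::group_by(bd, rule_id), n = sum(n))
  expect_equal(dplyr::arrange(agg, rule_id),
               dplyr::arrange(dplyr::rename(per_rule, n = n), rule_id),
               ignore_attr = TRUE)
  # empty records give an empty breakdown
  expect_equal(nrow(change_breakdown(rec[0, ])), 0L)
})
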