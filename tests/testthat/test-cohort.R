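test_that("index quarter is the earliest in-period C33/C34 quarter", {
  rec <- mk_rec(list(ev_dx("2015-08-10"), ev_dx("2016-02-01")))
  expect_equal(find_index_quarter(rec), quarter(2015, 3))
  expect_true(is.na(find_index_quarter(mk_rec(list(ev_ct("2015-08-10"))))))
  # diagnosis before the index period does not create an index quarter
  expect_true(is.na(find_index_quarter(mk_rec(list(ev_dx("2014-11-01"))))))
  # C33 qualifies like C34, as do 4-character children
  expect_equal(find_index_quarter(mk_rec(list(ev_dx("2015-02-01", code = "C331")))),
               quarter(2015, 1))
})

test_that("washout flips exactly at the eight-quarter boundary", {
  base <- list(ev_dx("2015-05-01"))
  rec_in <- mk_rec(c(base, list(ev_dx("2013-08-01"))), enr_start = "2012-01-01")  # index-7
  rec_edge <- mk_rec(c(base, list(ev_dx("2013-04-01"))), enr_start = "2012-01-01") # index-8
  rec_out <- mk_rec(c(base, list(ev_dx("2013-03-31"))), enr_start = "2012-01-01")  # index-9
  iq <- quarter(2015, 2)
  expect_false(is_newly_diagnosed(rec_in, iq))
  expect_false(is_newly_diagnosed(rec_edge, iq))
  expect_true(is_newly_diagnosed(rec_out, iq))
  expect_true(is_newly_diagnosed(mk_rec(base), iq))
})

test_that("confirmation needs two outpatient quarters or one confirmed inpatient coding", {
  iq <- quarter(2015, 2)
  m2q <- mk_rec(list(ev_dx("2015-05-01"), ev_dx("2015-11-15")))
  expect_true(confirm_diagnosis(m2q, iq))
  single <- mk_rec(list(ev_dx("2015-05-01")))
  expect_false(confirm_diagnosis(single, iq))
  same_q <- mk_rec(list(ev_dx("2015-05-01"), ev_dx("2015-06-20")))
  expect_false(confirm_diagnosis(same_q, iq))   # two codings, one quarter
  inpat <- mk_rec(list(ev_dx("2015-05-01", setting = "inpatient", provider = "hospital",
                             confirmed = TRUE)))
  expect_true(confirm_diagnosis(inpat, iq))
  inpat_uncf <- mk_rec(list(ev_dx("2015-05-01", setting = "inpatient",
                                  provider = "hospital", confirmed = FALSE)))
  expect_false(confirm_diagnosis(inpat_uncf, iq))
  # confirming coding beyond the observation horizon does not count
  late <- mk_rec(list(ev_dx("2015-05-01"), ev_dx("2019-02-01")), enr_end = "2019-12-31")
  expect_false(confirm_diagnosis(late, iq))
  expect_true(confirm_diagnosis(late, iq, obs_end = as.Date("2019-12-31")))
})

test_that("exclusion cascade applies checks in fixed order with one reason each", {
  iq <- quarter(2015, 2)
  confirmed <- list(ev_dx("2015-05-01", setting = "inpatient", provider = "hospital",
                          confirmed = TRUE), ev_dx("2015-08-10"))
  # other primary tumour within +/- 8 quarters
  rec <- mk_rec(c(confirmed, list(ev_dx("2016-02-01", code = "C50"))))
  expect_equal(apply_exclusions(rec, iq)$exclusion_reason, "other_primary_tumor")
  # C61 and C44 are exempt; C77 metastasis codes are not primaries
  rec <- mk_rec(c(confirmed, list(ev_dx("2016-02-01", code = "C61"),
                                  ev_dx("2016-02-01", code = "C44"),
                                  ev_dx("2015-05-01", code = "C77"))))
  expect_equal(apply_exclusions(rec, iq)$status, "included")
  # other primary outside the +/- 8 quarter window is ignored
  rec <- mk_rec(c(confirmed, list(ev_dx("2017-07-01", code = "C50"))))
  expect_equal(apply_exclusions(rec, iq)$status, "included")
  # 5 quarters of pre-observation are not enough
  rec <- mk_rec(confirmed, enr_start = "2014-01-01")
  expect_equal(apply_exclusions(rec, iq)$exclusion_reason, "insufficient_pre_observation")
  # enrollment ending inside the index quarter fails post-observation
  rec <- mk_rec(confirmed, enr_end = "2015-06-30")
  expect_equal(apply_exclusions(rec, iq)$exclusion_reason, "insufficient_post_observation")
  # unconfirmed beats every later reason (first failing check wins)
  rec <- mk_rec(list(ev_dx("2015-05-01"), ev_dx("2016-02-01", code = "C50")),
                enr_start = "2014-01-01")
  expect_equal(apply_exclusions(rec, iq)$exclusion_reason, "not_confirmed")
})

test_that("stage assignment: distant dominates lymph node dominates none", {
  iq <- quarter(2015, 2)
  expect_equal(assign_stage(mk_rec(list(ev_dx("2015-05-01"))), iq), "no_mets")
  expect_equal(assign_stage(mk_rec(list(ev_dx("2015-05-01"),
                                        ev_dx("2015-05-01", code = "C77"))), iq),
               "lymph_node_mets")
  expect_equal(assign_stage(mk_rec(list(ev_dx("2015-05-01"),
                                        ev_dx("2015-05-01", code = "C77"),
                                        ev_dx("2015-06-01", code = "C78"))), iq),
               "distant_mets")
  # metastasis coding outside the index quarter does not stage
  expect_equal(assign_stage(mk_rec(list(ev_dx("2015-05-01"),
                                        ev_dx("2015-08-01", code = "C78"))), iq),
               "no_mets")
})

test_that("age groups split at 60 (inclusive) and missing birth year is reported", {
  iq <- quarter(2015, 2)
  expect_equal(stratify_demographics(mk_rec(birth_year = 1955L), iq)$age_group, "<=60")
  expect_equal(stratify_demographics(mk_rec(birth_year = 1954L), iq)$age_group, ">60")
  expect_equal(stratify_demographics(mk_rec(birth_year = NA), iq)$age_group, "unknown")
})

test_that("pipeline exclusion reasons equal the generator's planned reasons", {
  pop <- generate_population(scenario_config(n_patients = 300, seed = 17))
  sel <- select_cohort(pop$claims)
  m <- merge(sel, pop$truth, by = "patient_id")
  cand <- m[m$status != "no_index", ]
  expect_identical(cand$exclusion_reason, cand$planned_exclusion_reason)
  # conservation: included + excluded = candidates
  expect_equal(sum(cand$status == "included") + sum(cand$status == "excluded"), nrow(cand))
  # non-candidates carry no lung-cancer coding
  expect_true(all(!m$is_incident_lc[m$status == "no_index"]))
})
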