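iq <- quarter(2015, 2)
confirm_ev <- list(ev_dx("2015-04-05", setting = "inpatient", provider = "hospital",
                         confirmed = TRUE), ev_dx("2015-09-10"))

test_that("first-line episode opens at the earliest therapy event in index/index+1", {
  rec <- mk_rec(c(confirm_ev, list(ev_rx("2015-04-10", "L01XC18"))))
  fl <- detect_first_line(rec, iq, shared_codes)
  expect_equal(fl$start, as.Date("2015-04-10"))
  expect_equal(fl$window_end, as.Date("2015-05-10"))
  expect_equal(fl$group, "Immunotherapy")
  # therapy starting two quarters after index is not first line
  rec <- mk_rec(c(confirm_ev, list(ev_rx("2015-10-05", "L01XA02"))))
  expect_null(detect_first_line(rec, iq, shared_codes))
  expect_null(detect_first_line(mk_rec(confirm_ev), iq, shared_codes))
  # radiotherapy EBM codes can open a line; unpaired study primaries cannot
  rec <- mk_rec(c(confirm_ev, list(ev_px("2015-05-02", "EBM", "25321"))))
  expect_equal(detect_first_line(rec, iq, shared_codes)$group, "Radiotherapy")
  rec <- mk_rec(c(confirm_ev, list(ev_px("2015-05-02", "EBM", "13461"))))
  expect_null(detect_first_line(rec, iq, shared_codes))
})

test_that("group assignment is hierarchical over the window", {
  rec <- mk_rec(c(confirm_ev, list(ev_rx("2015-04-10", "L01XC18"),
                                   ev_rx("2015-04-12", "L01XA02"))))
  expect_equal(detect_first_line(rec, iq, shared_codes)$group, "Immunotherapy")
  rec <- mk_rec(c(confirm_ev, list(ev_rx("2015-04-10", "L01XE03"),
                                   ev_rx("2015-04-12", "L01XA02"),
                                   ev_px("2015-04-15", "EBM", "25321"))))
  expect_equal(detect_first_line(rec, iq, shared_codes)$group, "Inhibitors")
  # study primary + companion in the same quarter form the Study group
  rec <- mk_rec(c(confirm_ev, list(ev_px("2015-05-02", "EBM", "13461"),
                                   ev_px("2015-05-20", "EBM", "02100"))))
  expect_equal(detect_first_line(rec, iq, shared_codes)$group, "Study")
  # generic inpatient chemotherapy OPS gives group Chemotherapy
  rec <- mk_rec(c(confirm_ev, list(ev_px("2015-04-20", "OPS", "8-5420",
                                         setting = "inpatient", provider = "hospital"))))
  expect_equal(detect_first_line(rec, iq, shared_codes)$group, "Chemotherapy")
})

test_that("second line opens at the first new code after the first-line window", {
  base <- c(confirm_ev, list(ev_rx("2015-04-10", "L01XA02")))
  # new drug after the window opens a second line
  rec <- mk_rec(c(base, list(ev_rx("2015-06-01", "L01XE03"))))
  fl <- detect_first_line(rec, iq, shared_codes)
  sl <- detect_second_line(rec, fl, shared_codes)
  expect_equal(sl$start, as.Date("2015-06-01"))
  expect_equal(sl$group, "Inhibitors")
  # repeats of first-line drugs never trigger
  rec <- mk_rec(c(base, list(ev_rx("2015-06-01", "L01XA02"),
                             ev_rx("2015-08-01", "L01XA02"))))
  fl <- detect_first_line(rec, iq, shared_codes)
  expect_null(detect_second_line(rec, fl, shared_codes))
  # same group, different drug: patient re-enters Chemotherapy
  rec <- mk_rec(c(base, list(ev_rx("2015-06-15", "L01BC05"))))
  fl <- detect_first_line(rec, iq, shared_codes)
  sl <- detect_second_line(rec, fl, shared_codes)
  expect_equal(sl$group, "Chemotherapy")
  # boundary: a new drug exactly 30 days after start is still first line
  rec30 <- mk_rec(c(confirm_ev, list(ev_rx("2015-04-10", "L01XA02"),
                                     ev_rx("2015-05-10", "L01BC05"))))
  fl30 <- detect_first_line(rec30, iq, shared_codes)
  expect_null(detect_second_line(rec30, fl30, shared_codes))
  rec31 <- mk_rec(c(confirm_ev, list(ev_rx("2015-04-10", "L01XA02"),
                                     ev_rx("2015-05-11", "L01BC05"))))
  fl31 <- detect_first_line(rec31, iq, shared_codes)
  expect_equal(detect_second_line(rec31, fl31, shared_codes)$start, as.Date("2015-05-11"))
})

test_that("cancer type follows the unambiguous-tag rule across lines", {
  ep <- function(...) {
    rec <- mk_rec(c(confirm_ev, list(...)))
    fl <- detect_first_line(rec, iq, shared_codes)
    list(fl = fl, sl = detect_second_line(rec, fl, shared_codes))
  }
  e <- ep(ev_rx("2015-04-10", "L01XC18"))
  expect_equal(classify_cancer_type(e$fl, e$sl),
               list(call = "NSCLC", basis = "first_line", conflicting = FALSE))
  # untyped first line, typed second line: decided by second line
  e <- ep(ev_rx("2015-04-10", "L01XA01"), ev_rx("2015-06-20", "L01XX17"))
  expect_equal(classify_cancer_type(e$fl, e$sl),
               list(call = "SCLC", basis = "second_line", conflicting = FALSE))
  # mixed tags in the deciding window: unclassifiable, conflicting
  e <- ep(ev_rx("2015-04-10", "L01XC18"), ev_rx("2015-04-15", "L01XA02"))
  expect_equal(classify_cancer_type(e$fl, e$sl)$call, "unclassifiable")
  expect_true(classify_cancer_type(e$fl, e$sl)$conflicting)
  # no therapy at all
  expect_equal(classify_cancer_type(NULL, NULL),
               list(call = "unclassifiable", basis = "none", conflicting = FALSE))
  # typed drug outside any line window leaves the patient unclassifiable
  rec <- mk_rec(c(confirm_ev, list(ev_rx("2015-10-05", "L01XC18"))))
  fl <- detect_first_line(rec, iq, shared_codes)
  expect_null(fl)
  expect_equal(classify_cancer_type(fl, NULL)$call, "unclassifiable")
})

test_that("untreated patients fall through the other-treatment cascade in order", {
  cat_of <- function(...) categorize_untreated(mk_rec(c(confirm_ev, list(...))),
                                               iq, shared_codes)
  # inpatient application marker within a month of the index quarter
  expect_equal(cat_of(ev_px("2015-07-10", "OPS", "8-5410", setting = "inpatient",
                            provider = "hospital")), "other_treatment")
  # therapy documented only after the line windows
  expect_equal(cat_of(ev_rx("2015-11-20", "L01XA02")), "late_therapy")
  # surgery in the observation phase, lung cancer re-coded later
  expect_equal(cat_of(ev_px("2015-05-05", "OPS", "5-3240", setting = "inpatient",
                            provider = "hospital")), "surgery_no_therapy")
  # bronchoscopy only
  expect_equal(cat_of(ev_px("2015-05-05", "OPS", "1-6200")),
               "bronchoscopy_no_surgery_no_therapy")
  expect_equal(cat_of(), "none_of_the_above")
  # no follow-up documentation at all after the index quarter
  rec <- mk_rec(list(ev_dx("2015-04-05", setting = "inpatient", provider = "hospital",
                           confirmed = TRUE)))
  expect_equal(categorize_untreated(rec, iq, shared_codes), "not_observable_in_line")
  # follow-up exists but lung cancer never re-coded
  rec <- mk_rec(list(ev_dx("2015-04-05", setting = "inpatient", provider = "hospital",
                           confirmed = TRUE), ev_ct("2015-09-01")))
  expect_equal(categorize_untreated(rec, iq, shared_codes), "no_followup_diagnosis")
})

test_that("every included patient gets exactly one first-line label", {
  pop <- inject_edge_cases(generate_population(scenario_config(n_patients = 120, seed = 23)))
  sel <- select_cohort(pop$claims)
  ln <- build_lines(pop$claims, sel, shared_codes)
  inc <- sel$patient_id[sel$status == "included"]
  expect_setequal(ln$labels$patient_id, inc)
  expect_false(anyDuplicated(ln$labels$patient_id) > 0)
  expect_true(all(ln$labels$first_line_label %in%
                    c(names(lungclaims:::GROUP_PRIORITY), lungclaims:::OTHER_CATEGORIES)))
  # types exist for every included patient too
  expect_setequal(ln$types$patient_id, inc)
})

test_that("line construction matches the brute-force day-by-day oracle", {
  pop <- inject_edge_cases(generate_population(scenario_config(n_patients = 120, seed = 29)))
  sel <- select_cohort(pop$claims)
  inc <- sel[sel$status == "included", ]
  recs <- lungclaims:::split_records(pop$claims, inc$patient_id)
  mism <- 0L
  for (i in seq_len(nrow(inc))) {
    rec <- recs[[inc$patient_id[i]]]
    iq_i <- quarter_parse(inc$index_quarter[i])
    fl <- detect_first_line(rec, iq_i, shared_codes)
    sl <- detect_second_line(rec, fl, shared_codes)
    or <- oracle_lines(rec, iq_i, shared_codes)
    ok <- if (is.null(fl)) is.null(or) else {
      !is.null(or) &&
        identical(fl$start, or$first$start) &&
        identical(fl$window_end, or$first$window_end) &&
        identical(fl$group, or$first$group) &&
        (is.null(sl) == is.null(or$second)) &&
        (is.null(sl) || (identical(sl$start, or$second$start) &&
                           identical(sl$group, or$second$group)))
    }
    if (!isTRUE(ok)) mism <- mism + 1L
  }
  expect_identical(mism, 0L)
})
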