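iq <- quarter(2015, 2)

test_that("therapist attribution follows the institution hierarchy", {
  rec <- mk_rec(list(ev_dx("2015-04-05", setting = "inpatient", provider = "hospital"),
                     ev_dx("2015-05-01", provider = "pulmonologist")))
  expect_equal(attribute_therapist(rec, iq)$category, "hospital_inpatient")
  rec <- mk_rec(list(ev_dx("2015-04-05", setting = "outpatient", provider = "hospital"),
                     ev_dx("2015-05-01", provider = "oncologist")))
  expect_equal(attribute_therapist(rec, iq)$category, "hospital_outpatient")
  rec <- mk_rec(list(ev_dx("2015-05-01", provider = "primary_care")))
  th <- attribute_therapist(rec, iq)
  expect_equal(th$category, "other_physician")
  expect_equal(th$specialty, "primary_care")
  # specialty order within office-based physicians
  rec <- mk_rec(list(ev_dx("2015-05-01", provider = "internist"),
                     ev_dx("2015-05-02", provider = "pulmonologist")))
  expect_equal(attribute_therapist(rec, iq)$specialty, "pulmonologist")
  # no coder in the quarter
  rec <- mk_rec(list(ev_dx("2015-08-01")))
  expect_equal(attribute_therapist(rec, iq)$category, "unknown")
  # permutation invariance within the quarter
  evs <- list(ev_dx("2015-05-01", provider = "radiologist"),
              ev_dx("2015-04-02", setting = "outpatient", provider = "hospital"),
              ev_dx("2015-06-20", provider = "oncologist"))
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1)))
    expect_equal(attribute_therapist(mk_rec(evs[perm]), iq)$category, "hospital_outpatient")
})

test_that("biomarker detection and the 14-day inpatient lookback boundary", {
  w <- matrix(c(quarter_start(iq), quarter_end(iq)), ncol = 2)
  test_day <- as.Date("2015-05-01")
  base <- list(ev_px("2015-05-01", "EBM", "19321"))
  # discharge exactly 14 days before the test: inpatient
  rec <- mk_rec(base, stays = list(mk_stay("2015-04-10", test_day - 14)))
  expect_equal(detect_biomarker(rec, w, shared_codes)$setting, "inpatient")
  # discharge 15 days before: outpatient
  rec <- mk_rec(base, stays = list(mk_stay("2015-04-10", test_day - 15)))
  expect_equal(detect_biomarker(rec, w, shared_codes)$setting, "outpatient")
  # OPS child of the 1-991 family counts; no stay means outpatient
  rec <- mk_rec(list(ev_px("2015-05-01", "OPS", "1-9910")))
  det <- detect_biomarker(rec, w, shared_codes)
  expect_true(det$detected)
  expect_equal(det$setting, "outpatient")
  # nothing in the window
  rec <- mk_rec(list(ev_px("2015-08-01", "EBM", "19321")))
  expect_equal(detect_biomarker(rec, w, shared_codes)$setting, "none")
})

test_that("bronchoscopy windows separate first- and second-line contexts", {
  confirm_ev <- list(ev_dx("2015-04-05", setting = "inpatient", provider = "hospital",
                           confirmed = TRUE), ev_dx("2015-09-10"))
  # first line starts 2015-07-20 (index+1 quarter), second line 2015-09-18;
  # a bronchoscopy 45 days after first-line start sits in the second-line
  # context (past the first month, before a month after second-line start)
  evs <- c(confirm_ev, list(ev_rx("2015-07-20", "L01XA02"),
                            ev_rx("2015-09-18", "L01XE03"),
                            ev_px("2015-09-03", "EBM", "13662")))
  claims <- mk_rec(evs)$claims
  sel <- select_cohort(claims)
  ln <- build_lines(claims, sel, shared_codes)
  care <- attribute_care(claims, sel, ln, shared_codes)
  expect_equal(care$bronchoscopy_first, "none")
  expect_equal(care$bronchoscopy_second, "outpatient")
  # but inside the index quarter the test is assigned to the first-line
  # context even when it falls after the first month of therapy
  evs_idx <- c(confirm_ev, list(ev_rx("2015-04-20", "L01XA02"),
                                ev_rx("2015-06-19", "L01XE03"),
                                ev_px("2015-06-04", "EBM", "13662")))
  claims_idx <- mk_rec(evs_idx)$claims
  sel_idx <- select_cohort(claims_idx)
  ln_idx <- build_lines(claims_idx, sel_idx, shared_codes)
  care_idx <- attribute_care(claims_idx, sel_idx, ln_idx, shared_codes)
  expect_equal(care_idx$bronchoscopy_first, "outpatient")
  expect_equal(care_idx$bronchoscopy_second, "none")
  # a bronchoscopy in the index quarter lands in the first-line context
  evs2 <- c(confirm_ev, list(ev_px("2015-05-05", "OPS", "1-6200")))
  claims2 <- mk_rec(evs2)$claims
  sel2 <- select_cohort(claims2)
  ln2 <- build_lines(claims2, sel2, shared_codes)
  care2 <- attribute_care(claims2, sel2, ln2, shared_codes)
  expect_equal(care2$bronchoscopy_first, "outpatient")
  expect_equal(care2$bronchoscopy_second, "none")
})

test_that("surgery is flagged only in the index or first-line start quarter", {
  confirm_ev <- list(ev_dx("2015-04-05", setting = "inpatient", provider = "hospital",
                           confirmed = TRUE), ev_dx("2015-09-10"))
  rec <- mk_rec(c(confirm_ev, list(ev_px("2015-05-05", "OPS", "5-3240"))))
  expect_true(detect_surgery(rec, iq, NULL, shared_codes))
  # surgery three quarters later is outside the observation phase
  rec <- mk_rec(c(confirm_ev, list(ev_px("2016-02-05", "OPS", "5-3240"))))
  expect_false(detect_surgery(rec, iq, NULL, shared_codes))
  # but counts when first-line therapy starts in that quarter
  expect_true(detect_surgery(rec, iq, list(start = as.Date("2016-02-01")), shared_codes))
  expect_false(detect_surgery(mk_rec(confirm_ev), iq, NULL, shared_codes))
  # an empty surgery set warns and detects nothing
  nosurg <- shared_codes[shared_codes$role != "surgery", ]
  rec <- mk_rec(c(confirm_ev, list(ev_px("2015-05-05", "OPS", "5-3240"))))
  expect_warning(res <- detect_surgery(rec, iq, NULL, nosurg), "empty")
  expect_false(res)
})
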