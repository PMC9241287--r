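#' @keywords internal
THERAPIST_SPECIALTY_ORDER <- c("oncologist", "pulmonologist", "radiologist",
                               "internist", "primary_care", "other_office_based")

#' Attribute the treating institution ("therapist") for a quarter
#'
#' Among the providers coding C33/C34 in the given quarter, the therapist is
#' picked by hierarchy: inpatient hospital stay > outpatient hospital stay >
#' office-based physician (oncologist > pulmonologist > radiologist >
#' internist > primary-care physician > other office-based physician). If no
#' one coded the diagnosis in that quarter the therapist is unknown.
#'
#' @param rec per-patient record.
#' @param qo quarter ordinal to attribute.
#' @return list with `category` (`"hospital_inpatient"`,
#'   `"hospital_outpatient"`, `"other_physician"`, `"unknown"`) and
#'   `specialty` (provider name or `NA`).
#' @export
attribute_therapist <- function(rec, qo) {
  ev <- rec$events
  dx <- ev[is_lc_dx(ev) & quarter_of(ev$date) == qo, , drop = FALSE]
  if (!nrow(dx)) return(list(category = "unknown", specialty = NA_character_))
  if (any(dx$provider == "hospital" & dx$setting == "inpatient"))
    return(list(category = "hospital_inpatient", specialty = "hospital"))
  if (any(dx$provider == "hospital" & dx$setting == "outpatient"))
    return(list(category = "hospital_outpatient", specialty = "hospital"))
  for (sp in THERAPIST_SPECIALTY_ORDER)
    if (any(dx$provider == sp))
      return(list(category = "other_physician", specialty = sp))
  list(category = "unknown", specialty = NA_character_)
}

# windows: two-column matrix of Dates (lo, hi), rows are a union of closed
# intervals
in_windows <- function(dates, windows) {
  if (is.null(windows) || !nrow(windows)) return(rep(FALSE, length(dates)))
  out <- rep(FALSE, length(dates))
  for (i in seq_len(nrow(windows)))
    out <- out | (dates >= windows[i, 1L] & dates <= windows[i, 2L])
  out
}

detect_diagnostic <- function(rec, windows, codes, what, lookback = 14L,
                              exclude = NULL) {
  ev <- rec$events
  ev <- ev[ev$kind == "procedure", , drop = FALSE]
  if (nrow(ev)) {
    idx <- match_codes(codes, ev$system, ev$code)
    role <- ifelse(is.na(idx), NA_character_, codes$role[idx])
    hit <- ev[!is.na(role) & role == what & in_windows(ev$date, windows) &
                !in_windows(ev$date, exclude), , drop = FALSE]
  } else hit <- ev
  if (!nrow(hit)) return(list(detected = FALSE, setting = "none", date = as.Date(NA)))
  d <- min(hit$date)
  st <- rec$stays
  inpat <- nrow(st) && any(st$admission <= d & st$discharge >= d - lookback)
  list(detected = TRUE, setting = if (inpat) "inpatient" else "outpatient", date = d)
}

#' Detect biomarker testing in a set of date windows
#'
#' Flags the biomarker billing codes (EBM 19320/19321/19322, OPS 1-991x and
#' 1-992x families). A detected test counts as inpatient if a hospital stay
#' overlaps the two weeks (14 days) before the test date, otherwise as
#' outpatient -- ambulatory care can be billed with inpatient OPS codes.
#'
#' @inheritParams attribute_therapist
#' @param windows two-column matrix of `Date`s, each row a closed interval;
#'   the union of rows is the search window.
#' @param codes a [load_code_table()] table.
#' @param lookback inpatient-attribution lookback in days (default 14).
#' @param exclude optional window matrix; dates inside it are ignored (used
#'   to keep the first- and second-line search contexts disjoint).
#' @return list with `detected`, `setting` (`"inpatient"`, `"outpatient"`,
#'   `"none"`) and `date` (earliest test, or `NA`).
#' @export
detect_biomarker <- function(rec, windows, codes, lookback = 14L, exclude = NULL) {
  detect_diagnostic(rec, windows, codes, "biomarker", lookback, exclude)
}

#' Detect diagnostic bronchoscopy in a set of date windows
#'
#' Same mechanics as [detect_biomarker()] with the bronchoscopy code set
#' (OPS 1-690.0/1-690.1/1-620, EBM 09315/13662).
#'
#' @inheritParams detect_biomarker
#' @export
detect_bronchoscopy <- function(rec, windows, codes, lookback = 14L, exclude = NULL) {
  detect_diagnostic(rec, windows, codes, "bronchoscopy", lookback, exclude)
}

#' Detect a surgical intervention
#'
#' Flags any surgery-role OPS code billed in the index quarter or in the
#' quarter in which first-line therapy starts. The bundled surgery code set
#' is a synthetic placeholder; supply a validated list for real analyses.
#'
#' @inheritParams attribute_therapist
#' @param index_q index quarter ordinal.
#' @param first first-line episode or `NULL`.
#' @param codes a [load_code_table()] table.
#' @return TRUE/FALSE.
#' @export
detect_surgery <- function(rec, index_q, first = NULL, codes) {
  if (!any(codes$role == "surgery")) {
    warning("surgery code set is empty; no surgery can be detected")
    return(FALSE)
  }
  qs <- index_q
  if (!is.null(first)) qs <- unique(c(qs, quarter_of(first$start)))
  ev <- rec$events
  ev <- ev[ev$kind == "procedure" & quarter_of(ev$date) %in% qs, , drop = FALSE]
  if (!nrow(ev)) return(FALSE)
  idx <- match_codes(codes, ev$system, ev$code)
  any(!is.na(idx) & codes$role[idx] == "surgery")
}

#' Therapist attribution and diagnostics for a cohort
#'
#' For every included patient: therapist at the index quarter and at the
#' first-/second-line start quarters, biomarker and bronchoscopy detection in
#' the first-line context (index quarter plus first month of first-line
#' therapy) and the second-line context (one month after first-line start to
#' one month after second-line start), and the surgery flag.
#'
#' @param claims a [claims_data()] object.
#' @param selection output of [select_cohort()].
#' @param lines output of [build_lines()].
#' @param codes a [load_code_table()] table.
#' @param window line window in days; `lookback` inpatient lookback in days.
#' @param lookback see above.
#' @return data.frame, one row per included patient.
#' @export
attribute_care <- function(claims, selection, lines, codes = load_code_table(),
                           window = 30L, lookback = 14L) {
  inc <- selection[selection$status == "included", , drop = FALSE]
  recs <- split_records(claims, inc$patient_id)
  ln <- lines$lines
  rows <- lapply(seq_len(nrow(inc)), function(i) {
    pid <- inc$patient_id[i]
    iq <- quarter_parse(inc$index_quarter[i])
    rec <- recs[[pid]]
    pl <- ln[ln$patient_id == pid, , drop = FALSE]
    fl_start <- if (any(pl$line == "first")) pl$start[pl$line == "first"] else as.Date(NA)
    sl_start <- if (any(pl$line == "second")) pl$start[pl$line == "second"] else as.Date(NA)

    th_idx <- attribute_therapist(rec, iq)
    th_fl <- if (!is.na(fl_start)) attribute_therapist(rec, quarter_of(fl_start))
             else list(category = "unknown", specialty = NA_character_)
    th_sl <- if (!is.na(sl_start)) attribute_therapist(rec, quarter_of(sl_start))
             else list(category = "unknown", specialty = NA_character_)

    w1 <- matrix(c(quarter_start(iq), quarter_end(iq)), ncol = 2L)
    if (!is.na(fl_start))
      w1 <- rbind(w1, c(fl_start, fl_start + window))
    w2 <- if (!is.na(fl_start) && !is.na(sl_start))
      matrix(c(fl_start + window + 1L, sl_start + window), ncol = 2L) else NULL

    bio1 <- detect_biomarker(rec, w1, codes, lookback)
    bro1 <- detect_bronchoscopy(rec, w1, codes, lookback)
    bio2 <- if (!is.null(w2)) detect_biomarker(rec, w2, codes, lookback, exclude = w1)
            else list(detected = FALSE, setting = "none")
    bro2 <- if (!is.null(w2)) detect_bronchoscopy(rec, w2, codes, lookback, exclude = w1)
            else list(detected = FALSE, setting = "none")

    fl_ep <- if (!is.na(fl_start)) list(start = fl_start) else NULL
    surg <- detect_surgery(rec, iq, fl_ep, codes)

    data.frame(patient_id = pid,
               therapist_index = th_idx$category, therapist_index_specialty = th_idx$specialty,
               therapist_first_line = th_fl$category, therapist_second_line = th_sl$category,
               biomarker_first = bio1$setting, biomarker_second = bio2$setting,
               bronchoscopy_first = bro1$setting, bronchoscopy_second = bro2$setting,
               surgery = surg)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patient_id = character(0), therapist_index = character(0),
                      therapist_index_specialty = character(0),
                      therapist_first_line = character(0), therapist_second_line = character(0),
                      biomarker_first = character(0), biomarker_second = character(0),
                      bronchoscopy_first = character(0), bronchoscopy_second = character(0),
                      surgery = logical(0))
  rownames(out) <- NULL
  out
}
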